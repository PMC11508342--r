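make_sub_series <- function(frames, fr = 4) {
  structure(list(frames = frames, frame_rate = fr, mask_policy = "test"),
            class = "subtracted_series")
}

test_that("a one-pixel ROI reproduces that pixel's time course", {
  set.seed(21)
  f <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  s <- make_sub_series(f)
  tdc <- extract_tdc(s, roi(1, row = 3, col = 4, radius = 0.5))
  expect_equal(tdc$values, f[, 3, 4])
  expect_equal(tdc$times, (0:7) / 4)
  expect_equal(tdc$source, "ccDSA")
})

test_that("an all-zero series gives an all-zero curve", {
  s <- make_sub_series(array(0, c(6, 5, 5)))
  expect_true(all(extract_tdc(s, roi(2, 3, 3, 2))$values == 0))
})

test_that("ROI means match a pixel-enumeration oracle", {
  set.seed(22)
  f <- array(rnorm(5 * 9 * 9), c(5, 9, 9))
  s <- make_sub_series(f)
  r <- roi(1, row = 4.6, col = 5.2, radius = 2.3)
  tdc <- extract_tdc(s, r)
  # independent oracle: enumerate all pixels, test the disk inequality
  for (t in 1:5) {
    acc <- c()
    for (i in 1:9) for (j in 1:9) {
      if ((i - r$row)^2 + (j - r$col)^2 <= r$radius^2) acc <- c(acc, f[t, i, j])
    }
    expect_equal(tdc$values[t], mean(acc), tolerance = 1e-12)
  }
  # uniform disk of value v at one frame -> curve value v there
  f2 <- array(0, c(5, 9, 9))
  for (i in 1:9) for (j in 1:9) {
    if ((i - r$row)^2 + (j - r$col)^2 <= r$radius^2) f2[3, i, j] <- 7.5
  }
  expect_equal(extract_tdc(make_sub_series(f2), r)$values,
               c(0, 0, 7.5, 0, 0))
  expect_error(extract_tdc(s, roi(3, row = 50, col = 50, radius = 2)),
               "outside")
})

test_that("TTP follows frame quantization at both clinical frame rates", {
  mk <- function(peak_frame, fr, n = 20) {
    v <- numeric(n); v[peak_frame + 1] <- 1  # 0-based peak index
    structure(list(times = (0:(n - 1)) / fr, values = v,
                   source = "ccDSA", roi_serial = 1L),
              class = "time_density_curve")
  }
  expect_equal(compute_ttp(mk(10, 4))$ttp, 2.5)
  expect_equal(compute_ttp(mk(10, 7.5))$ttp, 10 / 7.5, tolerance = 1e-12)
  r <- compute_ttp(mk(10, 4))
  expect_equal(r$peak_index, 10L)
  expect_equal(r$ttp, r$peak_index / 4)
})

test_that("flat curves resolve ties to the first frame", {
  cv <- structure(list(times = (0:9) / 4, values = rep(3, 10),
                       source = "ccDVA", roi_serial = 2L),
                  class = "time_density_curve")
  expect_equal(compute_ttp(cv)$ttp, 0)
  expect_error(compute_ttp(cv, smoothing_window = 2), "odd")
})

test_that("TTP is invariant under positive affine rescaling of the curve", {
  set.seed(23)
  for (i in 1:10) {
    v <- cumsum(rnorm(15))
    cv <- structure(list(times = (0:14) / 7.5, values = v,
                         source = "ccDSA", roi_serial = 1L),
                    class = "time_density_curve")
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    cv2 <- cv; cv2$values <- a * v + b
    for (w in c(1, 3)) {
      expect_equal(compute_ttp(cv, w)$ttp, compute_ttp(cv2, w)$ttp)
    }
  }
})

test_that("passage time subtracts proximal from distal TTP and is antisymmetric", {
  t1 <- structure(list(ttp = 2, peak_value = 1, peak_index = 8L,
                       roi_serial = 1L), class = "ttp_result")
  t4 <- structure(list(ttp = 5, peak_value = 1, peak_index = 20L,
                       roi_serial = 4L), class = "ttp_result")
  p <- compute_passage_time(t1, t4, "pre")
  expect_equal(p$passage_time, 3)
  t4b <- t4; t4b$ttp <- t1$ttp
  expect_equal(compute_passage_time(t1, t4b)$passage_time, 0)
  # antisymmetry under swapping the two TTP values
  t1s <- t1; t1s$ttp <- t4$ttp
  t4s <- t4; t4s$ttp <- t1$ttp
  expect_equal(compute_passage_time(t1s, t4s)$passage_time,
               -p$passage_time)
  expect_error(compute_passage_time(t4, t1), "serial")
})

test_that("change in passage time is pre minus post, with phase checking", {
  mk <- function(pt, phase) structure(list(passage_time = pt, phase = phase),
                                      class = "passage_record")
  expect_equal(compute_delta_passage(mk(3, "pre"), mk(1.8, "post")), 1.2)
  expect_equal(compute_delta_passage(mk(2, "pre"), mk(2, "post")), 0)
  expect_error(compute_delta_passage(mk(2, "post"), mk(2, "post")), "phase")
})

test_that("measured passage time matches the velocity-profile integral", {
  for (fr in c(4, 7.5)) for (sf in c(0.45, 0.9)) {
    sp <- tiny_spec(frame_rate = fr, stenosis_factor = sf)
    sim <- simulate_acquisition(sp)
    dsa <- compute_dsa(sim$series, 2)
    ttps <- lapply(sp$rois, function(r) compute_ttp(extract_tdc(dsa, r)))
    p <- compute_passage_time(ttps[[1]], ttps[[4]], "pre")
    expect_lt(abs(p$passage_time - true_passage_time(sp)), 1 / fr + 1e-9)
  }
})

test_that("noise-free deltas from a paired cohort are all positive", {
  ch <- make_study_cohort(n_acquisitions = 4, seed = 5L, n_three_roi = 0,
                          noise = "none")
  for (pair in ch) {
    ttp_at <- function(spec) {
      sim <- simulate_acquisition(spec)
      dsa <- compute_dsa(sim$series, 2)
      vapply(spec$rois, function(r) compute_ttp(extract_tdc(dsa, r))$ttp,
             numeric(1))
    }
    pre <- ttp_at(pair$pre); post <- ttp_at(pair$post)
    expect_gt((pre[4] - pre[1]) - (post[4] - post[1]), 0)
  }
})

test_that("noise-free TTPs recover ground truth within one frame interval", {
  for (fr in c(4, 7.5)) {
    sp <- tiny_spec(frame_rate = fr)
    sim <- simulate_acquisition(sp)
    dsa <- compute_dsa(sim$series, 2)
    dva <- compute_dva_series(sim$series, 3, "trailing")
    for (r in sp$rois) {
      truth <- sim$truth$roi_true_ttp[[as.character(r$serial)]]
      for (proc in list(dsa, dva)) {
        est <- compute_ttp(extract_tdc(proc, r))$ttp
        expect_lt(abs(est - truth), 1 / fr + 1e-9,
                  label = sprintf("%s ROI%d @ %g FPS",
                                  class(proc)[1], r$serial, fr))
      }
    }
  }
})

test_that("rendering orders hue by arrival and blanks silent pixels", {
  f <- array(0, c(6, 2, 2))
  f[2, 1, 1] <- 1   # early pixel
  f[5, 2, 1] <- 1   # late pixel
  pm <- render_parametric_image(make_sub_series(f), amplitude_floor = 0.05)
  # hue angle: red (0) for earliest, toward blue for latest
  hue_of <- function(i, j) {
    rgb <- pm$rgb_image[i, j, ]
    grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1)[1]
  }
  expect_lt(hue_of(1, 1), hue_of(2, 1))
  # the two never-enhancing pixels are black
  expect_true(all(pm$rgb_image[1, 2, ] == 0))
  expect_true(all(pm$rgb_image[2, 2, ] == 0))
  expect_equal(pm$colorbar_range, c(1 / 4, 4 / 4))

  pm0 <- render_parametric_image(make_sub_series(array(0, c(6, 3, 3))))
  expect_true(all(pm0$rgb_image == 0))
})

test_that("per-pixel rendered TTP equals compute_ttp on single-pixel curves", {
  set.seed(24)
  f <- array(abs(rnorm(10 * 4 * 4)), c(10, 4, 4))
  s <- make_sub_series(f)
  pm <- render_parametric_image(s)
  for (i in 1:4) for (j in 1:4) {
    cv <- extract_tdc(s, roi(1, i, j, 0.5))
    expect_equal(pm$ttp_map[i, j], compute_ttp(cv)$ttp)
  }
})

test_that("hue rank agreement with TTP is exact on a noise-free phantom", {
  sp <- tiny_spec()
  sim <- simulate_acquisition(sp)
  dsa <- compute_dsa(sim$series, 2)
  pm <- render_parametric_image(dsa)
  sel <- !is.na(pm$hue_map)
  expect_equal(cor(rank(pm$hue_map[sel]), rank(pm$ttp_map[sel])), 1)
  # the 8-bit rendering preserves the ordering almost exactly
  hue8 <- apply(pm$rgb_image, c(1, 2), function(v) {
    grDevices::rgb2hsv(v[1], v[2], v[3], maxColorValue = 1)[1]
  })
  expect_gt(cor(rank(hue8[sel]), rank(pm$ttp_map[sel])), 0.99)
  # and hue ordering tracks true arrival strongly
  arr <- sim$truth$arrival_time_map
  ok <- sel & !is.na(arr)
  expect_gt(cor(pm$hue_map[ok], arr[ok], method = "spearman"), 0.99)
})

test_that("degenerate time range renders a single hue with a warning", {
  f <- array(0, c(5, 2, 2))
  f[3, , ] <- 1  # every pixel peaks at the same frame
  expect_warning(pm <- render_parametric_image(make_sub_series(f)),
                 "degenerate")
  expect_true(all(pm$rgb_image[, , 1] == 1))  # pure red everywhere
  expect_true(all(pm$rgb_image[, , 2:3] == 0))
})
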