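test_that("constant series give all-zero variance map and series", {
  s <- constant_series(value = 42)
  expect_true(all(compute_dva_map(s)$values == 0))
  expect_true(all(compute_dva_series(s, 3)$frames == 0))
})

test_that("alternating pixel has the closed-form standard deviation", {
  a <- 10; b <- 4
  f <- array(0, c(8, 2, 2))
  f[, 1, 1] <- rep(c(a, b), 4)
  f[, 2, 1] <- 7
  s <- frame_series(f, 4)
  m <- compute_dva_map(s)
  expect_equal(m$values[1, 1], abs(a - b) / 2, tolerance = 1e-12)
  expect_equal(m$values[2, 1], 0)
})

test_that("variance map matches a two-pass textbook oracle exactly", {
  set.seed(11)
  f <- array(rnorm(3 * 3 * 10, mean = 5), c(10, 3, 3))
  s <- frame_series(f, 4)
  got <- compute_dva_map(s)$values
  oracle <- apply(f, c(2, 3), function(v) {
    mu <- mean(v)
    sqrt(sum((v - mu)^2) / length(v))  # population convention
  })
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("windowed sd matches the brute-force oracle for every policy", {
  set.seed(12)
  f <- array(rnorm(12 * 2 * 2, 100, 10), c(12, 2, 2))
  s <- frame_series(f, 4)
  for (L in c(2, 3, 5, 12)) {
    for (al in c("trailing", "centered")) {
      for (ed in c("truncate", "shift")) {
        got <- compute_dva_series(s, L, al, ed)
        for (p in 1:2) {
          expect_equal(got$frames[, p, 1],
                       brute_window_sd(f[, p, 1], L, al, ed),
                       tolerance = 1e-9,
                       label = sprintf("L=%d %s %s pixel %d", L, al, ed, p))
        }
      }
    }
  }
})

test_that("full-length window reproduces the variance map", {
  set.seed(13)
  f <- array(rnorm(10 * 3 * 2, 50, 5), c(10, 3, 2))
  s <- frame_series(f, 4)
  m <- compute_dva_map(s)$values
  # shifted edges keep the full window everywhere: every frame equals the map
  vs <- compute_dva_series(s, 10, "trailing", edge = "shift")
  for (t in 1:10) expect_equal(vs$frames[t, , ], m, tolerance = 1e-9)
  # truncated edges agree wherever the window is complete
  vt <- compute_dva_series(s, 10, "trailing", edge = "truncate")
  expect_equal(vt$frames[10, , ], m, tolerance = 1e-9)
})

test_that("variance obeys non-negativity, static-offset invariance and |c| scaling", {
  sp <- tiny_spec(noise = TRUE)
  s <- simulate_acquisition(sp)$series
  vm <- compute_dva_map(s)
  vs <- compute_dva_series(s, 3)
  expect_true(all(vm$values >= 0))
  expect_true(all(vs$frames >= 0))
  d <- dim(s$frames)
  static <- matrix(runif(d[2] * d[3], 0, 500), d[2], d[3])
  s2 <- s
  s2$frames <- s$frames + rep(static, each = d[1])
  expect_equal(compute_dva_map(s2)$values, vm$values, tolerance = 1e-9)
  expect_equal(compute_dva_series(s2, 3)$frames, vs$frames, tolerance = 1e-9)
  s3 <- s
  s3$frames <- s$frames * 2.5
  expect_equal(compute_dva_map(s3)$values, 2.5 * vm$values, tolerance = 1e-9)
  # |c| for negative scaling, checked on the raw arrays (constructor
  # rejects negative intensities by design)
  x <- matrix(s$frames, d[1], d[2] * d[3])[, 1000]
  expect_equal(brute_window_sd(-2 * x, 3), 2 * brute_window_sd(x, 3),
               tolerance = 1e-9)
})

test_that("noise-free phantom: variance map is positive exactly on traversed vessel pixels", {
  sp <- tiny_spec()
  sim <- simulate_acquisition(sp)
  vm <- compute_dva_map(sim$series)
  vessel <- !is.na(sim$truth$arrival_time_map)
  expect_true(all(vm$values[!vessel] == 0))
  # traversed = bolus rose above zero during the acquisition at a pixel
  # with non-zero chord depth (exact-boundary pixels carry no attenuation)
  arr <- sim$truth$arrival_time_map
  traversed <- vessel & (arr - sp$bolus_rise_time) < sp$duration &
    sim$truth$peak_attenuation_map > 0
  expect_true(all(vm$values[traversed] > 0))
})

test_that("windowed-sd argmax tracks the maximum-slope time", {
  sp <- tiny_spec()
  sim <- simulate_acquisition(sp)
  arr <- sim$truth$arrival_time_map
  d <- dim(sim$series$frames)
  x <- matrix(sim$series$frames, d[1], d[2] * d[3])
  times <- (seq_len(d[1]) - 1) / sp$frame_rate
  px <- which(!is.na(arr) & arr < sp$duration - sp$bolus_duration)
  L <- 5
  vs <- compute_dva_series(sim$series, L, "centered")
  v <- matrix(vs$frames, d[1], d[2] * d[3])
  for (p in px[seq(1, length(px), by = 23)]) {
    slope_t <- times[which.max(abs(diff(x[, p])))] + 0.5 / sp$frame_rate
    sd_peak_t <- times[which.max(v[, p])]
    expect_lt(abs(sd_peak_t - slope_t), L / sp$frame_rate + 1e-9)
  }
})

test_that("window validation rejects out-of-range input", {
  s <- constant_series(n = 6)
  expect_error(compute_dva_series(s, 1), "window_length")
  expect_error(compute_dva_series(s, 7), "window_length")
  f <- array(1, c(4, 2, 2))
  short <- frame_series(f, 4)
  expect_silent(compute_dva_map(short))
})
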