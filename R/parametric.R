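#' Circular region of interest
#'
#' A round ROI identified by a serial number. In the standard placement
#' scheme ROI1 lies proximal to the lesion, ROI2 at the lesion start, ROI3
#' at the lesion end and ROI4 distal to it; passage-time computations use
#' serials 1 and 4.
#'
#' @param serial Integer serial number, 1-4.
#' @param row,col Center coordinates in pixels (may be sub-pixel).
#' @param radius ROI radius in pixels (> 0).
#' @return An object of class `roi`.
#' @export
roi <- function(serial, row, col, radius) {
  serial <- as.integer(serial)
  if (is.na(serial) || serial < 1L || serial > 4L) {
    stop("ROI serial must be an integer in 1..4")
  }
  if (radius <= 0) stop("ROI radius must be positive")
  structure(list(serial = serial, row = row, col = col, radius = radius),
            class = "roi")
}

#' Collect ROIs into a set with unique serials
#'
#' @param x A list of [roi()] objects (or several rois given as `...`).
#' @param ... Further rois.
#' @return A list of class `roi_set`.
#' @export
roi_set <- function(x, ...) {
  rois <- if (is.list(x) && !inherits(x, "roi")) c(x, list(...)) else list(x, ...)
  stopifnot(all(vapply(rois, inherits, TRUE, "roi")))
  serials <- vapply(rois, `[[`, 0L, "serial")
  if (anyDuplicated(serials)) stop("ROI serials must be unique within a set")
  structure(rois[order(serials)], class = "roi_set")
}

#' Pixels covered by a circular ROI
#'
#' Enumerates the pixels whose centers lie within the ROI disk
#' (`(row - center_row)^2 + (col - center_col)^2 <= radius^2`) and that fall
#' inside an image of the given size.
#'
#' @param roi A [roi()].
#' @param height,width Image size in pixels.
#' @return Integer vector of flat pixel indices into a `height x width`
#'   matrix (column-major).
#' @export
roi_pixels <- function(roi, height, width) {
  rlo <- max(1, floor(roi$row - roi$radius))
  rhi <- min(height, ceiling(roi$row + roi$radius))
  clo <- max(1, floor(roi$col - roi$radius))
  chi <- min(width, ceiling(roi$col + roi$radius))
  if (rlo > rhi || clo > chi) {
    stop(sprintf("ROI %d lies fully outside the image", roi$serial))
  }
  r0 <- rlo:rhi
  c0 <- clo:chi
  gr <- expand.grid(r = r0, c = c0)
  keep <- (gr$r - roi$row)^2 + (gr$c - roi$col)^2 <= roi$radius^2
  px <- gr$r[keep] + (gr$c[keep] - 1L) * height
  if (length(px) == 0) {
    stop(sprintf("ROI %d covers no pixel inside the image", roi$serial))
  }
  as.integer(px)
}

#' Extract a time-density curve for one ROI
#'
#' The TDC value at frame `t` is the arithmetic mean of the processed signal
#' over the ROI's pixels: attenuation-proxy units for a subtracted series
#' (ccDSA) and windowed-sd units for a variance series (ccDVA). Times are
#' seconds from the start of acquisition, `frame_index / frame_rate`.
#'
#' @param series A `subtracted_series` or `variance_series` (a raw
#'   [frame_series()] is also accepted).
#' @param roi A [roi()] intersecting the image.
#' @return A `time_density_curve`: `times`, `values`, `source` (one of
#'   `"ccDSA"`, `"ccDVA"`, `"raw"`) and `roi_serial`.
#' @export
extract_tdc <- function(series, roi) {
  stopifnot(is_series(series), inherits(roi, "roi"))
  d <- dim(series$frames)
  px <- roi_pixels(roi, d[2], d[3])
  x <- as_time_matrix(series$frames)
  vals <- if (length(px) == 1L) x[, px] else rowMeans(x[, px, drop = FALSE])
  src <- switch(class(series)[1],
                subtracted_series = "ccDSA",
                variance_series = "ccDVA",
                "raw")
  structure(
    list(times = series_times(series), values = vals,
         source = src, roi_serial = roi$serial),
    class = "time_density_curve"
  )
}

#' @export
print.time_density_curve <- function(x, ...) {
  cat(sprintf("<time_density_curve> %s, ROI %d, %d frames (%.2f s)\n",
              x$source, x$roi_serial, length(x$values), max(x$times)))
  invisible(x)
}

# moving average with truncated windows at the series edges; w = 1 is a no-op
moving_average <- function(v, w) {
  if (w == 1L) return(v)
  h <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(v)
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Time to peak of a time-density curve
#'
#' TTP is the time from the start of acquisition to the maximum of the TDC:
#' after optional moving-average smoothing the peak frame is
#' `argmax(values)` with ties broken by the earliest frame, and
#' `ttp = peak_index / frame_rate`. No subframe interpolation is applied by
#' default; `refine = TRUE` adds a three-point parabolic refinement of the
#' peak time (the reported `peak_index` stays frame-quantized).
#'
#' @param curve A `time_density_curve` (from [extract_tdc()]).
#' @param smoothing_window Odd moving-average window in frames; 1 (default)
#'   disables smoothing.
#' @param refine Logical; parabolic subframe refinement of the peak time.
#' @return A `ttp_result`: `ttp` (seconds), `peak_value` (curve units at the
#'   peak of the possibly smoothed curve), `peak_index` (0-based frame
#'   index) and `roi_serial`.
#' @export
compute_ttp <- function(curve, smoothing_window = 1, refine = FALSE) {
  stopifnot(inherits(curve, "time_density_curve"))
  n <- length(curve$values)
  if (n == 0) stop("empty time-density curve")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop("smoothing_window must be an odd integer >= 1")
  }
  v <- moving_average(curve$values, as.integer(smoothing_window))
  i <- which.max(v)  # earliest frame on ties
  dt <- curve$times[2] - curve$times[1]
  ttp <- curve$times[i]
  if (refine && i > 1 && i < n) {
    a <- v[i - 1]; b <- v[i]; cc <- v[i + 1]
    den <- a - 2 * b + cc
    if (den < 0) ttp <- ttp + dt * 0.5 * (a - cc) / den
  }
  structure(
    list(ttp = ttp, peak_value = v[i], peak_index = i - 1L,
         roi_serial = curve$roi_serial),
    class = "ttp_result"
  )
}

#' @export
print.ttp_result <- function(x, ...) {
  cat(sprintf("<ttp_result> ROI %d: TTP = %.3f s (frame %d, peak %.4g)\n",
              x$roi_serial, x$ttp, x$peak_index, x$peak_value))
  invisible(x)
}

#' Bolus passage time across the target area
#'
#' The difference between the distal and proximal time to peak,
#' `TTP(ROI4) - TTP(ROI1)`: the time the bolus needs to flow across the
#' lesion. May be negative; no clamping is applied.
#'
#' @param ttp_roi1 `ttp_result` for the proximal ROI (serial 1).
#' @param ttp_roi4 `ttp_result` for the distal ROI (serial 4).
#' @param phase Acquisition phase, `"pre"` or `"post"` intervention.
#' @return A `passage_record` with `passage_time` (seconds) and `phase`.
#' @export
compute_passage_time <- function(ttp_roi1, ttp_roi4,
                                 phase = c("pre", "post")) {
  phase <- match.arg(phase)
  stopifnot(inherits(ttp_roi1, "ttp_result"), inherits(ttp_roi4, "ttp_result"))
  if (ttp_roi1$roi_serial != 1L || ttp_roi4$roi_serial != 4L) {
    stop(sprintf("expected ROI serials 1 and 4, got %d and %d",
                 ttp_roi1$roi_serial, ttp_roi4$roi_serial))
  }
  structure(
    list(passage_time = ttp_roi4$ttp - ttp_roi1$ttp, phase = phase),
    class = "passage_record"
  )
}

#' Change in passage time with intervention
#'
#' `pre passage time - post passage time`: positive when treatment
#' accelerates the bolus transit, which is the expected effect of
#' angioplasty or stenting.
#'
#' @param pre,post `passage_record`s with phases `"pre"` and `"post"`.
#' @return Change in passage time, seconds.
#' @export
compute_delta_passage <- function(pre, post) {
  stopifnot(inherits(pre, "passage_record"), inherits(post, "passage_record"))
  if (pre$phase != "pre" || post$phase != "post") {
    stop(sprintf("expected phases 'pre' and 'post', got '%s' and '%s'",
                 pre$phase, post$phase))
  }
  pre$passage_time - post$passage_time
}

#' Render a color-coded parametric image
#'
#' Per-pixel TTP (argmax over time, earliest frame on ties) and peak
#' amplitude are extracted from a processed series and rendered as an HSV
#' image: hue runs linearly from red (earliest arrival) through the
#' spectrum to blue (latest) over `[t_min, t_max]`, and brightness is
#' proportional to the peak amplitude normalized at its 99th percentile and
#' clipped at 1. `[t_min, t_max]` is computed from pixels whose amplitude
#' exceeds `amplitude_floor` times that 99th-percentile amplitude;
#' sub-floor pixels are rendered black. A degenerate time range (all
#' selected pixels peak simultaneously) renders a single-hue image with a
#' warning.
#'
#' @param series A `subtracted_series` or `variance_series`.
#' @param amplitude_floor Fraction of the 99th-percentile amplitude below
#'   which pixels are considered background.
#' @return A `parametric_map`: `ttp_map` (seconds per pixel),
#'   `amplitude_map` (peak signal per pixel, >= 0), `hue_map` (exact hue
#'   angle in `[0, 2/3]`, `NA` for sub-floor pixels; the `rgb_image` is its
#'   8-bit rendering), `rgb_image` (height x width x 3 array in `[0, 1]`)
#'   and `colorbar_range` (`c(t_min, t_max)` seconds).
#' @export
render_parametric_image <- function(series, amplitude_floor = 0.05) {
  stopifnot(is_series(series))
  d <- dim(series$frames)
  x <- as_time_matrix(series$frames)
  peak_idx <- max.col(t(x), ties.method = "first")
  times <- series_times(series)
  ttp <- times[peak_idx]
  amp <- x[cbind(peak_idx, seq_len(ncol(x)))]
  amp <- pmax(amp, 0)

  q99 <- stats::quantile(amp, 0.99, names = FALSE)
  sel <- q99 > 0 & amp > amplitude_floor * q99
  if (!any(sel)) {
    rgb_img <- array(0, c(d[2], d[3], 3))
    return(structure(
      list(ttp_map = matrix(ttp, d[2], d[3]),
           amplitude_map = matrix(amp, d[2], d[3]),
           hue_map = matrix(NA_real_, d[2], d[3]),
           rgb_image = rgb_img, colorbar_range = c(NA_real_, NA_real_)),
      class = "parametric_map"
    ))
  }
  t_min <- min(ttp[sel]); t_max <- max(ttp[sel])
  if (t_min == t_max) {
    warning("degenerate arrival-time range: rendering a single-hue image")
    hue <- rep(0, length(ttp))
  } else {
    hue <- (2 / 3) * (ttp - t_min) / (t_max - t_min)
    hue <- pmin(pmax(hue, 0), 2 / 3)
  }
  val <- pmin(amp / q99, 1)
  val[!sel] <- 0
  cols <- grDevices::hsv(h = hue, s = 1, v = val)
  rgbm <- grDevices::col2rgb(cols) / 255
  rgb_img <- array(0, c(d[2], d[3], 3))
  rgb_img[, , 1] <- matrix(rgbm[1, ], d[2], d[3])
  rgb_img[, , 2] <- matrix(rgbm[2, ], d[2], d[3])
  rgb_img[, , 3] <- matrix(rgbm[3, ], d[2], d[3])
  hue_map <- matrix(hue, d[2], d[3])
  hue_map[matrix(!sel, d[2], d[3])] <- NA_real_
  structure(
    list(ttp_map = matrix(ttp, d[2], d[3]),
         amplitude_map = matrix(amp, d[2], d[3]),
         hue_map = hue_map,
         rgb_image = rgb_img, colorbar_range = c(t_min, t_max)),
    class = "parametric_map"
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %d x %d px, color range %.2f-%.2f s\n",
              nrow(x$ttp_map), ncol(x$ttp_map),
              x$colorbar_range[1], x$colorbar_range[2]))
  invisible(x)
}

#' Write a parametric map to PNG with an embedded color bar
#'
#' @param map A `parametric_map` from [render_parametric_image()].
#' @param path Output PNG path.
#' @param bar_width Width of the embedded color bar in pixels (0 to omit).
#' @return `path`, invisibly.
#' @export
write_parametric_png <- function(map, path, bar_width = 8) {
  img <- map$rgb_image
  if (bar_width > 0 && !anyNA(map$colorbar_range)) {
    H <- dim(img)[1]
    hue <- (2 / 3) * (seq_len(H) - 1) / max(1, H - 1)  # red (top) -> blue
    colm <- grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255
    bar <- array(0, c(H, bar_width + 2, 3))
    for (ch in 1:3) bar[, seq_len(bar_width) + 2, ch] <- colm[ch, ]
    out <- array(0, c(H, dim(img)[2] + bar_width + 2, 3))
    out[, seq_len(dim(img)[2]), ] <- img
    out[, dim(img)[2] + seq_len(bar_width + 2), ] <- bar
    img <- out
  }
  png::writePNG(img, path)
  invisible(path)
}
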