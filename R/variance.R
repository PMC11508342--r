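#' Digital variance angiography map
#'
#' The DVA image: per-pixel standard deviation of the intensity time course
#' over the whole raw (unsubtracted) series, population convention (divisor
#' `N`). Moving contrast produces high temporal variance while stationary
#' background gives values near zero, so the map shows the vasculature
#' without any mask subtraction.
#'
#' @param series A [frame_series()] (or any series object) with at least 2
#'   frames.
#' @return A `variance_map`: `values` (height x width matrix, detector
#'   intensity units, all `>= 0`) and `window = "full_series"`.
#' @export
compute_dva_map <- function(series) {
  stopifnot(is_series(series))
  if (n_frames(series) < 2) stop("need at least 2 frames for a variance map")
  x <- as_time_matrix(series$frames)
  m <- colMeans(x)
  v <- sqrt(pmax(0, colMeans(sweep(x, 2, m, "-")^2)))
  d <- dim(series$frames)
  structure(
    list(values = matrix(v, d[2], d[3]), window = "full_series"),
    class = "variance_map"
  )
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("<variance_map> %d x %d px (window: %s)\n",
              nrow(x$values), ncol(x$values), x$window))
  invisible(x)
}

#' Time-resolved (sliding-window) variance series
#'
#' Extends the DVA map to a frame-by-frame signal: output frame `t` is the
#' per-pixel standard deviation (population convention) over a window of
#' frames ending at `t` (`"trailing"`, default) or centered on `t`
#' (`"centered"`). A pixel's windowed-sd time course peaks where its
#' intensity changes fastest -- for a bolus with a sub-frame opacification
#' front this is the contrast arrival itself, which is what makes the ccDVA
#' time-density curve comparable to the subtracted pathway's.
#'
#' Two edge policies are available: `"truncate"` (default) computes edge
#' frames on the partial window that fits inside the series, `"shift"`
#' slides the window inward so every frame uses exactly `window_length`
#' frames (with `window_length` equal to the series length this makes every
#' output frame identical to [compute_dva_map()]).
#'
#' @param series A [frame_series()] (or any series object).
#' @param window_length Window length in frames, `2 <= window_length <=`
#'   number of frames.
#' @param window_alignment `"trailing"` (causal window ending at `t`) or
#'   `"centered"` (window of `2 * floor(window_length / 2) + 1` frames
#'   symmetric about `t`).
#' @param edge `"truncate"` or `"shift"` (see Details).
#' @return A `variance_series` with the same frame count as the source,
#'   `frame_rate` copied, and the window parameters recorded.
#' @export
compute_dva_series <- function(series, window_length = 3,
                               window_alignment = c("trailing", "centered"),
                               edge = c("truncate", "shift")) {
  window_alignment <- match.arg(window_alignment)
  edge <- match.arg(edge)
  stopifnot(is_series(series))
  T <- n_frames(series)
  if (window_length < 2 || window_length > T) {
    stop(sprintf("window_length must be in [2, %d], got %s", T, window_length))
  }
  x <- as_time_matrix(series$frames)
  # center each pixel on its series mean: windowed sd is unchanged and the
  # running-sum computation loses far less precision
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr, "-")
  cs <- apply(x, 2, cumsum)
  cs2 <- apply(x * x, 2, cumsum)
  if (window_alignment == "trailing") {
    lo <- pmax(1L, seq_len(T) - as.integer(window_length) + 1L)
    hi <- seq_len(T)
    if (edge == "shift") hi <- pmax(hi, as.integer(window_length))
  } else {
    h <- window_length %/% 2
    lo <- seq_len(T) - h
    hi <- seq_len(T) + h
    if (edge == "shift") {
      shift <- pmax(0L, 1L - lo) - pmax(0L, hi - T)
      lo <- lo + shift
      hi <- hi + shift
    }
    lo <- pmax(1L, lo)
    hi <- pmin(T, hi)
  }
  out <- matrix(0, T, ncol(x))
  for (t in seq_len(T)) {
    m <- hi[t] - lo[t] + 1L
    S <- cs[hi[t], ] - if (lo[t] > 1L) cs[lo[t] - 1L, ] else 0
    S2 <- cs2[hi[t], ] - if (lo[t] > 1L) cs2[lo[t] - 1L, ] else 0
    out[t, ] <- sqrt(pmax(0, S2 / m - (S / m)^2))
  }
  dim(out) <- dim(series$frames)
  structure(
    list(
      frames = out,
      frame_rate = series$frame_rate,
      window_length = as.integer(window_length),
      window_alignment = window_alignment,
      edge = edge
    ),
    class = "variance_series"
  )
}

#' @export
print.variance_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<variance_series> %d frames of %d x %d px @ %g FPS (window %d, %s, %s edges)\n",
    d[1], d[2], d[3], x$frame_rate, x$window_length, x$window_alignment, x$edge
  ))
  invisible(x)
}
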