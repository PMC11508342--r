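#' Mask-subtraction DSA of a raw frame series
#'
#' Classical digital subtraction angiography: a mask formed from the first
#' `mask_frames` pre-contrast frames is subtracted from every frame, removing
#' all static anatomy so only the moving contrast signal remains. By default
#' the subtraction is done in negative-log (attenuation) space, where
#' Beer-Lambert contrast is additive: the mask is the pixelwise mean of
#' `-log(frame)` over the mask frames and the output at frame `t` is
#' `-log(frame_t) - mask`, so contrast arrival is positive and a stationary
#' noise-free background maps to exactly 0. With `domain = "linear"` the
#' mask is the mean detector value and the output is `mask - frame_t` (same
#' sign convention).
#'
#' @param series A [frame_series()]; for the log domain all intensities must
#'   be strictly positive.
#' @param mask_frames Number of leading frames averaged into the mask
#'   (`1 <= mask_frames < number of frames`).
#' @param domain `"log"` (default, attenuation space) or `"linear"`
#'   (detector space).
#' @return A `subtracted_series`: frames in attenuation-proxy units (contrast
#'   positive), `frame_rate` copied from the source, and a `mask_policy`
#'   label recording how the mask was formed.
#' @export
compute_dsa <- function(series, mask_frames = 2, domain = c("log", "linear")) {
  domain <- match.arg(domain)
  stopifnot(is_series(series))
  T <- n_frames(series)
  if (mask_frames < 1 || mask_frames >= T) {
    stop(sprintf("mask_frames must be in [1, %d), got %s", T, mask_frames))
  }
  x <- as_time_matrix(series$frames)
  if (domain == "log") {
    bad <- which(x <= 0)
    if (length(bad)) {
      b <- arrayInd(bad[1], dim(x))
      d <- dim(series$frames)
      px <- arrayInd(b[2], c(d[2], d[3]))
      stop(sprintf(
        "non-positive intensity at frame %d, pixel (%d, %d): log-domain subtraction needs strictly positive detector values",
        b[1], px[1], px[2]
      ))
    }
    x <- -log(x)
    mask <- colMeans(x[seq_len(mask_frames), , drop = FALSE])
    out <- sweep(x, 2, mask, "-")
  } else {
    mask <- colMeans(x[seq_len(mask_frames), , drop = FALSE])
    out <- sweep(-x, 2, mask, "+")  # mask - frame
  }
  dim(out) <- dim(series$frames)
  structure(
    list(
      frames = out,
      frame_rate = series$frame_rate,
      mask_policy = sprintf("mean_first_%d_frames_%s", mask_frames, domain)
    ),
    class = "subtracted_series"
  )
}

#' @export
print.subtracted_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<subtracted_series> %d frames of %d x %d px @ %g FPS (mask: %s)\n",
              d[1], d[2], d[3], x$frame_rate, x$mask_policy))
  invisible(x)
}
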