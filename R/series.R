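#' Angiographic frame series
#'
#' Container for a time-ordered stack of grayscale frames, the raw
#' (unsubtracted) acquisition of an angiographic run. Frames are stored as a
#' numeric array with dimensions `time x height x width` so that a single
#' pixel's time course `frames[, i, j]` is contiguous in memory.
#'
#' @param frames Numeric array `time x height x width` of detector intensity
#'   units. All values must be non-negative and at least 4 frames are
#'   required.
#' @param frame_rate Acquisition frame rate in frames per second (> 0).
#' @param time_origin Label recording what `t = 0` refers to; either
#'   `"acquisition_start"` (default) or `"injection"`.
#'
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_rate,
                         time_origin = c("acquisition_start", "injection")) {
  time_origin <- match.arg(time_origin)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (time x height x width)")
  }
  if (dim(frames)[1] < 4L) {
    stop("a frame series needs at least 4 frames, got ", dim(frames)[1])
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number")
  }
  if (any(frames < 0)) stop("frame intensities must be non-negative")
  structure(
    list(frames = frames, frame_rate = frame_rate, time_origin = time_origin),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_series> %d frames of %d x %d px @ %g FPS (%.2f s, origin: %s)\n",
    d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate, x$time_origin
  ))
  invisible(x)
}

# frame times in seconds, origin at the series' time origin
series_times <- function(x) (seq_len(dim(x$frames)[1]) - 1) / x$frame_rate

n_frames <- function(x) dim(x$frames)[1]

# reshape T x H x W -> T x (H*W); columns are pixel time courses
as_time_matrix <- function(frames) {
  d <- dim(frames)
  dim(frames) <- c(d[1], d[2] * d[3])
  frames
}

is_series <- function(x) {
  inherits(x, c("frame_series", "subtracted_series", "variance_series"))
}
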