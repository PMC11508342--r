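#' Write a series to multipage TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled into `[0, 1]`; the
#' affine scaling (`value_offset`, `value_scale`) and all series metadata
#' (type, frame rate, time origin, mask policy or window parameters) go
#' into a JSON sidecar at `<path>.json`. [read_series()] reverses the
#' process.
#'
#' @param series A [frame_series()], `subtracted_series` or
#'   `variance_series`.
#' @param path Output TIFF path (sidecar written at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(is_series(series))
  f <- series$frames
  off <- min(f)
  sc <- max(f) - off
  if (sc == 0) sc <- 1
  pages <- lapply(seq_len(dim(f)[1]), function(t) (f[t, , ] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    type = class(series)[1],
    frame_rate = series$frame_rate,
    value_offset = off,
    value_scale = sc
  )
  for (nm in c("time_origin", "mask_policy", "window_length",
               "window_alignment", "edge")) {
    if (!is.null(series[[nm]])) meta[[nm]] <- series[[nm]]
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a series written by [write_series()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must exist and
#'   carry the frame-rate metadata (there is no silent default).
#' @return The reconstructed series object (class per the sidecar's `type`).
#' @export
read_series <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop("missing sidecar ", sc_path,
         ": frame_rate and series metadata are unavailable")
  }
  meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(meta$frame_rate)) {
    stop("sidecar ", sc_path, " carries no frame_rate")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (t in seq_along(pages)) {
    frames[t, , ] <- pages[[t]] * meta$value_scale + meta$value_offset
  }
  switch(meta$type,
    frame_series = frame_series(frames, meta$frame_rate,
                                meta$time_origin %||% "acquisition_start"),
    subtracted_series = structure(
      list(frames = frames, frame_rate = meta$frame_rate,
           mask_policy = meta$mask_policy %||% "unknown"),
      class = "subtracted_series"),
    variance_series = structure(
      list(frames = frames, frame_rate = meta$frame_rate,
           window_length = meta$window_length,
           window_alignment = meta$window_alignment %||% "trailing",
           edge = meta$edge %||% "truncate"),
      class = "variance_series"),
    stop("unknown series type in sidecar: ", meta$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write ROI sets as JSON
#'
#' The interchange format is a JSON array of objects
#' `{"serial": 1, "row": r, "col": c, "radius": px}`.
#'
#' @param rois A [roi_set()].
#' @param path JSON file path.
#' @return `write_roi_set()` returns `path` invisibly; `read_roi_set()`
#'   returns a [roi_set()].
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(serial = r$serial, row = r$row, col = r$col, radius = r$radius)
  }))
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(lapply(seq_len(nrow(df)), function(i) {
    roi(df$serial[i], df$row[i], df$col[i], df$radius[i])
  }))
}

#' Export time-density curves as CSV
#'
#' @param curves A `time_density_curve` or list of them.
#' @param path CSV path; columns `time_s`, `value`, `source`, `roi_serial`.
#' @return `path`, invisibly.
#' @export
write_tdc_csv <- function(curves, path) {
  if (inherits(curves, "time_density_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(time_s = cv$times, value = cv$values,
               source = cv$source, roi_serial = cv$roi_serial)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write phantom ground truth to plain files
#'
#' The arrival-time map goes to a 32-bit float TIFF (background pixels,
#' which have no arrival time, are stored as -1) and the per-ROI true TTPs
#' to a CSV.
#'
#' @param truth A `ground_truth` from [simulate_acquisition()].
#' @param path_prefix Output prefix; writes `<prefix>_arrival.tif` and
#'   `<prefix>_roi_truth.csv`.
#' @return The prefix, invisibly.
#' @export
write_ground_truth <- function(truth, path_prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- truth$arrival_time_map
  m[is.na(m)] <- -1
  off <- min(m)
  sc <- max(m) - off
  if (sc == 0) sc <- 1
  tiff::writeTIFF((m - off) / sc, paste0(path_prefix, "_arrival.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(value_offset = off, value_scale = sc,
                            background = -1),
                       paste0(path_prefix, "_arrival.tif.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth$roi_true_ttp)) {
    utils::write.csv(
      data.frame(roi_serial = as.integer(names(truth$roi_true_ttp)),
                 true_ttp_s = as.numeric(truth$roi_true_ttp)),
      paste0(path_prefix, "_roi_truth.csv"), row.names = FALSE
    )
  }
  invisible(path_prefix)
}
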