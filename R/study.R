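#' Configuration for a simulated comparison study
#'
#' Bundles and validates every parameter of the end-to-end experiment:
#' cohort size and frame rates, processing parameters for both pathways,
#' and output options. Validation happens here, before any computation.
#'
#' @param n_acquisitions Number of pre/post acquisition pairs.
#' @param frame_rates Frame rates assigned across the cohort (FPS).
#' @param seed Integer seed driving the whole study.
#' @param mask_frames Pre-contrast frames averaged into the DSA mask.
#' @param dsa_domain `"log"` or `"linear"` subtraction domain.
#' @param dva_window_length,dva_window_alignment Sliding-window parameters
#'   of the variance pathway (see [compute_dva_series()]).
#' @param smoothing_window Odd TDC moving-average window (1 = off).
#' @param amplitude_floor Rendering floor for [render_parametric_image()].
#' @param n_three_roi Pairs carrying only 3 ROIs.
#' @param noise `"default"` or `"none"` (noise-free cohort).
#' @param out_dir Output directory for CSV/Markdown/figure files, or `NULL`
#'   to keep everything in memory.
#' @param write_intermediates Write per-acquisition TIFF stacks and ROI
#'   JSON under `out_dir`.
#' @param render_maps Write color-coded PNG maps per acquisition.
#' @param verbose One log line per acquisition and stage.
#' @return A validated `study_config`.
#' @export
study_config <- function(n_acquisitions = 22,
                         frame_rates = c(4, 7.5),
                         seed = 1L,
                         mask_frames = 2,
                         dsa_domain = c("log", "linear"),
                         dva_window_length = 3,
                         dva_window_alignment = c("trailing", "centered"),
                         smoothing_window = 1,
                         amplitude_floor = 0.05,
                         n_three_roi = 3,
                         noise = c("default", "none"),
                         out_dir = NULL,
                         write_intermediates = FALSE,
                         render_maps = FALSE,
                         verbose = FALSE) {
  dsa_domain <- match.arg(dsa_domain)
  dva_window_alignment <- match.arg(dva_window_alignment)
  noise <- match.arg(noise)
  if (n_acquisitions < 1) stop("config field n_acquisitions must be >= 1")
  if (length(frame_rates) == 0) stop("config field frame_rates must not be empty")
  if (any(frame_rates <= 0)) stop("config field frame_rates must be positive")
  if (mask_frames < 1) stop("config field mask_frames must be >= 1")
  if (dva_window_length < 2) stop("config field dva_window_length must be >= 2")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop("config field smoothing_window must be an odd integer >= 1")
  }
  if (amplitude_floor < 0 || amplitude_floor >= 1) {
    stop("config field amplitude_floor must be in [0, 1)")
  }
  structure(
    list(n_acquisitions = n_acquisitions, frame_rates = frame_rates,
         seed = as.integer(seed), mask_frames = mask_frames,
         dsa_domain = dsa_domain, dva_window_length = dva_window_length,
         dva_window_alignment = dva_window_alignment,
         smoothing_window = smoothing_window,
         amplitude_floor = amplitude_floor, n_three_roi = n_three_roi,
         noise = noise, out_dir = out_dir,
         write_intermediates = write_intermediates,
         render_maps = render_maps, verbose = verbose),
    class = "study_config"
  )
}

process_acquisition <- function(spec, config) {
  sim <- simulate_acquisition(spec)
  dsa <- compute_dsa(sim$series, config$mask_frames, config$dsa_domain)
  dva <- compute_dva_series(sim$series, config$dva_window_length,
                            config$dva_window_alignment)
  ttp_one <- function(proc) {
    vapply(spec$rois, function(r) {
      compute_ttp(extract_tdc(proc, r), config$smoothing_window)$ttp
    }, numeric(1))
  }
  list(
    series = sim$series, truth = sim$truth, dsa = dsa, dva = dva,
    ttp_dsa = ttp_one(dsa), ttp_dva = ttp_one(dva),
    serials = vapply(spec$rois, `[[`, 0L, "serial")
  )
}

#' Run the full simulated comparison study
#'
#' Generates the paired cohort, processes every acquisition through both
#' pathways with identical ROI sets, extracts all TTPs and passage times,
#' and builds the grouped Pearson agreement table. With `out_dir` set it
#' also writes the TTP/delta/comparison CSVs, a Markdown table, scatter
#' plots of the two pathways' TTPs (by protocol and by ROI position) and
#' passage-time changes, and a JSON manifest recording the configuration
#' and package version; the run is fully reproducible from the manifest.
#'
#' @param config A [study_config()].
#' @return A `study_report` list: `ttp` (long data frame of both pathways'
#'   TTPs), `passage` (per-phase passage times), `deltas` (per-acquisition
#'   change in passage time per pathway), `comparison`
#'   ([build_comparison_table()] output) and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- make_study_cohort(
    n_acquisitions = config$n_acquisitions,
    frame_rates = config$frame_rates, paired = TRUE, seed = config$seed,
    n_three_roi = config$n_three_roi, noise = config$noise
  )
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  ttp_rows <- list(); passage_rows <- list()
  for (pair in cohort) {
    for (phase in c("pre", "post")) {
      spec <- pair[[phase]]
      res <- process_acquisition(spec, config)
      if (config$verbose) {
        message(sprintf(
          "acq %02d %-4s @ %g FPS: %d frames, %d ROIs [mask=%d, window=%d %s]",
          pair$id, phase, spec$frame_rate, n_frames(res$series),
          length(res$serials), config$mask_frames, config$dva_window_length,
          config$dva_window_alignment))
      }
      for (j in seq_along(res$serials)) {
        ttp_rows[[length(ttp_rows) + 1]] <- data.frame(
          acquisition = pair$id, phase = phase,
          roi_serial = res$serials[j], frame_rate = pair$frame_rate,
          ttp_dsa = res$ttp_dsa[j], ttp_dva = res$ttp_dva[j],
          true_ttp = unname(res$truth$roi_true_ttp[j])
        )
      }
      if (all(c(1L, 4L) %in% res$serials)) {
        i1 <- match(1L, res$serials); i4 <- match(4L, res$serials)
        passage_rows[[length(passage_rows) + 1]] <- data.frame(
          acquisition = pair$id, phase = phase,
          passage_dsa = res$ttp_dsa[i4] - res$ttp_dsa[i1],
          passage_dva = res$ttp_dva[i4] - res$ttp_dva[i1]
        )
      }
      if (!is.null(out_dir) && config$write_intermediates) {
        adir <- file.path(out_dir, sprintf("acq_%02d_%s", pair$id, phase))
        dir.create(adir, showWarnings = FALSE, recursive = TRUE)
        write_series(res$series, file.path(adir, "raw.tif"))
        write_series(res$dsa, file.path(adir, "dsa.tif"))
        write_series(res$dva, file.path(adir, "dva.tif"))
        write_roi_set(spec$rois, file.path(adir, "rois.json"))
        write_ground_truth(res$truth, file.path(adir, "truth"))
      }
      if (!is.null(out_dir) && config$render_maps) {
        adir <- file.path(out_dir, sprintf("acq_%02d_%s", pair$id, phase))
        dir.create(adir, showWarnings = FALSE, recursive = TRUE)
        write_parametric_png(
          render_parametric_image(res$dsa, config$amplitude_floor),
          file.path(adir, "ccdsa.png"))
        write_parametric_png(
          render_parametric_image(res$dva, config$amplitude_floor),
          file.path(adir, "ccdva.png"))
      }
    }
  }
  ttp <- do.call(rbind, ttp_rows)
  passage <- do.call(rbind, passage_rows)

  deltas <- NULL
  if (!is.null(passage)) {
    pre <- passage[passage$phase == "pre", ]
    post <- passage[passage$phase == "post", ]
    dm <- merge(pre, post, by = "acquisition", suffixes = c("_pre", "_post"))
    deltas <- data.frame(
      acquisition = dm$acquisition,
      delta_dsa = dm$passage_dsa_pre - dm$passage_dsa_post,
      delta_dva = dm$passage_dva_pre - dm$passage_dva_post
    )
  }

  split_cols <- function(df, col) {
    data.frame(acquisition = df$acquisition, phase = df$phase,
               roi_serial = df$roi_serial, frame_rate = df$frame_rate,
               ttp = df[[col]])
  }
  comparison <- build_comparison_table(
    split_cols(ttp, "ttp_dsa"), split_cols(ttp, "ttp_dva"),
    if (!is.null(deltas)) data.frame(acquisition = deltas$acquisition,
                                     delta = deltas$delta_dsa),
    if (!is.null(deltas)) data.frame(acquisition = deltas$acquisition,
                                     delta = deltas$delta_dva)
  )

  if (!is.null(out_dir)) {
    utils::write.csv(ttp, file.path(out_dir, "ttp.csv"), row.names = FALSE)
    utils::write.csv(passage, file.path(out_dir, "passage.csv"),
                     row.names = FALSE)
    if (!is.null(deltas)) {
      utils::write.csv(deltas, file.path(out_dir, "deltas.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    writeLines(format_comparison_md(comparison),
               file.path(out_dir, "comparison.md"))
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("angioflow")),
           config = config[setdiff(names(config), c("out_dir"))]),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    study_figures(ttp, deltas, out_dir)
  }

  structure(
    list(ttp = ttp, passage = passage, deltas = deltas,
         comparison = comparison, config = config),
    class = "study_report"
  )
}

study_figures <- function(ttp, deltas, out_dir) {
  scatter <- function(x, y, main) {
    lim <- range(c(x, y))
    graphics::plot(x, y, xlim = lim, ylim = lim, pch = 19,
                   col = grDevices::rgb(0.1, 0.3, 0.7, 0.6),
                   xlab = "ccDSA (s)", ylab = "ccDVA (s)", main = main)
    graphics::abline(0, 1, col = "grey50", lty = 2)
    r <- stats::cor(x, y)
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("r = %.4f (n = %d)", r, length(x)))
  }
  grDevices::png(file.path(out_dir, "ttp_by_protocol.png"),
                 width = 1200, height = 600, res = 120)
  rates <- sort(unique(ttp$frame_rate))
  graphics::par(mfrow = c(1, length(rates)))
  for (f in rates) {
    sub <- ttp[ttp$frame_rate == f, ]
    scatter(sub$ttp_dsa, sub$ttp_dva, sprintf("TTP, %g FPS", f))
  }
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "ttp_by_roi.png"),
                 width = 1200, height = 1200, res = 120)
  graphics::par(mfrow = c(2, 2))
  for (k in sort(unique(ttp$roi_serial))) {
    sub <- ttp[ttp$roi_serial == k, ]
    scatter(sub$ttp_dsa, sub$ttp_dva, sprintf("TTP, ROI%d", k))
  }
  grDevices::dev.off()

  if (!is.null(deltas) && nrow(deltas) >= 3) {
    grDevices::png(file.path(out_dir, "delta_passage.png"),
                   width = 600, height = 600, res = 120)
    scatter(deltas$delta_dsa, deltas$delta_dva, "Change in passage time")
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d acquisitions x 2 phases, %d TTP pairs\n",
              x$config$n_acquisitions, nrow(x$ttp)))
  print(x$comparison)
  invisible(x)
}
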