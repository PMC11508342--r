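#' Paired measurements from the two pathways
#'
#' @param x Values derived from the subtracted (ccDSA) pathway, seconds.
#' @param y Matched values from the variance (ccDVA) pathway, seconds.
#' @param group_label Text label for the comparison group.
#' @return A `paired_measurements` object.
#' @export
paired_measurements <- function(x, y, group_label = "") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 group_label = group_label, n = length(x)),
            class = "paired_measurements")
}

#' Pearson correlation report for one comparison group
#'
#' Computes the product-moment correlation `r`, its two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, the
#' 95% confidence interval by the Fisher z-transform with normal critical
#' value 1.96, and `R^2 = r^2`. For `|r| = 1` the Fisher interval is
#' degenerate and collapses to `r` itself.
#'
#' @param x A [paired_measurements()] object, or a numeric vector (with `y`
#'   supplied).
#' @param y Numeric vector matched to `x` (ignored when `x` is a
#'   `paired_measurements`).
#' @param group_label Label for the report (taken from `x` when it is a
#'   `paired_measurements`).
#' @return A `correlation_report`: `r`, `r_squared`, `ci_low`, `ci_high`,
#'   `p_two_tailed`, `n`, `group_label`.
#' @export
pearson_report <- function(x, y = NULL, group_label = "") {
  if (inherits(x, "paired_measurements")) {
    group_label <- x$group_label
    y <- x$y
    x <- x$x
  }
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("Pearson correlation needs at least 3 pairs, got ", n)
  if (stats::sd(x) == 0) stop("zero variance in x: correlation undefined")
  if (stats::sd(y) == 0) stop("zero variance in y: correlation undefined")
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) < 1) {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
  } else {
    p <- 0
    ci <- c(r, r)
  }
  structure(
    list(r = r, r_squared = r^2, ci_low = ci[1], ci_high = ci[2],
         p_two_tailed = p, n = n, group_label = group_label),
    class = "correlation_report"
  )
}

format_p <- function(p) {
  if (p < 1e-15) "< 1e-15" else sprintf("= %.3g", p)
}

#' @export
print.correlation_report <- function(x, ...) {
  lbl <- if (nzchar(x$group_label)) paste0(x$group_label, " ") else ""
  cat(sprintf(
    "<correlation_report> %s(n = %d): r = %.4f (95%% CI %.4f-%.4f), R2 = %.4f, p %s\n",
    lbl, x$n, x$r, x$ci_low, x$ci_high, x$r_squared, format_p(x$p_two_tailed)
  ))
  invisible(x)
}

as_report_row <- function(rep) {
  data.frame(
    group = rep$group_label, n = rep$n, r = rep$r,
    ci_low = rep$ci_low, ci_high = rep$ci_high,
    r_squared = rep$r_squared, p_two_tailed = rep$p_two_tailed,
    stringsAsFactors = FALSE
  )
}

#' Grouped agreement table between the two pathways
#'
#' Matches TTP results from the subtracted (ccDSA) and variance (ccDVA)
#' pathways by exact key -- acquisition, phase and ROI serial, never by
#' position -- and emits one Pearson [pearson_report()] per comparison
#' group: one per acquisition frame rate, one per ROI serial, the pooled
#' "all ROI" group, and (when passage-time changes are supplied) the change
#' in passage time matched by acquisition. Unmatched keys are excluded with
#' a message reporting their count.
#'
#' @param ttp_dsa,ttp_dva Data frames with columns `acquisition`, `phase`,
#'   `roi_serial`, `frame_rate`, `ttp` (seconds).
#' @param delta_dsa,delta_dva Optional data frames with columns
#'   `acquisition`, `delta` (seconds) holding each pathway's change in
#'   passage time.
#' @return A data frame of class `comparison_table` with one row per group:
#'   `group`, `n`, `r`, `ci_low`, `ci_high`, `r_squared`, `p_two_tailed`.
#' @export
build_comparison_table <- function(ttp_dsa, ttp_dva,
                                   delta_dsa = NULL, delta_dva = NULL) {
  need <- c("acquisition", "phase", "roi_serial", "frame_rate", "ttp")
  for (nm in list(ttp_dsa, ttp_dva)) {
    if (!all(need %in% names(nm))) {
      stop("TTP tables need columns: ", paste(need, collapse = ", "))
    }
  }
  m <- merge(ttp_dsa, ttp_dva,
             by = c("acquisition", "phase", "roi_serial"),
             suffixes = c("_dsa", "_dva"))
  n_unmatched <- nrow(ttp_dsa) + nrow(ttp_dva) - 2 * nrow(m)
  if (n_unmatched > 0) {
    message(sprintf("excluded %d unmatched TTP record(s)", n_unmatched))
  }
  if (nrow(m) == 0) stop("no matched TTP pairs")
  m$frame_rate <- m$frame_rate_dsa

  rows <- list()
  add_group <- function(x, y, label) {
    if (length(x) < 3) {
      message(sprintf("group '%s' has %d pair(s), fewer than 3: skipped",
                      label, length(x)))
      return(invisible(NULL))
    }
    rows[[length(rows) + 1]] <<- as_report_row(pearson_report(x, y, label))
  }
  for (f in sort(unique(m$frame_rate))) {
    sub <- m[m$frame_rate == f, ]
    add_group(sub$ttp_dsa, sub$ttp_dva, sprintf("TTP %g FPS", f))
  }
  for (k in sort(unique(m$roi_serial))) {
    sub <- m[m$roi_serial == k, ]
    add_group(sub$ttp_dsa, sub$ttp_dva, sprintf("TTP ROI%d", k))
  }
  add_group(m$ttp_dsa, m$ttp_dva, "TTP all ROI")

  if (!is.null(delta_dsa) && !is.null(delta_dva)) {
    dm <- merge(delta_dsa, delta_dva, by = "acquisition",
                suffixes = c("_dsa", "_dva"))
    du <- nrow(delta_dsa) + nrow(delta_dva) - 2 * nrow(dm)
    if (du > 0) message(sprintf("excluded %d unmatched passage record(s)", du))
    add_group(dm$delta_dsa, dm$delta_dva, "Delta passage time")
  }
  if (length(rows) == 0) stop("no group had at least 3 matched pairs")
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Pearson correlation of time parameters between pathways\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s (n=%3d)  r = %.4f  [%.4f, %.4f]  R2 = %.4f  p %s\n",
                x$group[i], x$n[i], x$r[i], x$ci_low[i], x$ci_high[i],
                x$r_squared[i], format_p(x$p_two_tailed[i])))
  }
  invisible(x)
}

#' Format a comparison table as Markdown
#'
#' @param table A `comparison_table` from [build_comparison_table()].
#' @return A character vector of Markdown lines.
#' @export
format_comparison_md <- function(table) {
  hdr <- c(
    "| Correlation Group (n) | Pearson r | 95% Confidence Interval | R2 | Two-Tailed p |",
    "|---|---|---|---|---|"
  )
  body <- vapply(seq_len(nrow(table)), function(i) {
    p <- table$p_two_tailed[i]
    ptxt <- if (p < 1e-15) "<1e-15" else sprintf("%.3g", p)
    sprintf("| %s (%d) | %.4f | %.4f-%.4f | %.4f | %s |",
            table$group[i], table$n[i], table$r[i],
            table$ci_low[i], table$ci_high[i], table$r_squared[i], ptxt)
  }, character(1))
  c(hdr, body)
}
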