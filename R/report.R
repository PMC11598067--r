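# Human-facing validation reports: pairing of reference and estimate
# tables, metric summaries, the extrapolation table row, and the per-view
# volume error report. Every report carries a provenance attribute
# (package version, configuration, seed where randomness is involved) so
# deterministic reports reproduce bit-for-bit.

with_provenance <- function(x, config, seed = NULL) {
  attr(x, "provenance") <- list(
    package = "berrymetrics",
    version = as.character(utils::packageVersion("berrymetrics")),
    config = config, seed = seed)
  x
}

pair_views <- function(reference, estimates, ref_col, est_col) {
  validate_annotations(reference)
  validate_annotations(estimates)
  if (!ref_col %in% names(reference))
    stop("reference table lacks column '", ref_col, "'")
  if (!est_col %in% names(estimates))
    stop("estimate table lacks column '", est_col, "'")
  m <- merge(reference[, c("bunch_id", "view_index", ref_col)],
             estimates[, c("bunch_id", "view_index", est_col)],
             by = c("bunch_id", "view_index"))
  if (nrow(m) != nrow(reference) || nrow(m) != nrow(estimates))
    stop("pairing error: reference and estimate tables do not match ",
         "one-to-one on (bunch_id, view_index)")
  m[order(m$bunch_id, m$view_index), ]
}

metrics_summary <- function(est, ref) {
  pe <- 100 * (est - ref) / ref
  list(k = length(est),
       me = mean_error(est, ref),
       sigma_e = error_sd(est, ref),
       mpe = mean_percentage_error(est, ref),
       mpe_sd = stats::sd(pe),
       mae = mae(est, ref),
       rmse = rmse(est, ref))
}

#' Counting and radius validation reports
#'
#' Pairs a reference annotation table with an estimate table on
#' `(bunch_id, view_index)` and reports ME, its standard deviation, MPE
#' (with sd), MAE and RMSE. `validate_counting()` compares `n_est`
#' against `n_visible`; with no arguments it runs on the packaged
#' fixture tables, reproducing the headline counting metrics of the
#' validation study (MPE of -4.67%, printed as -5%).
#' `validate_radius()` compares `r_mean_est_px` against `r_mean_px`.
#'
#' @param reference Reference annotations (default: [load_table1()]
#'   views for counting).
#' @param estimates Estimate table (default: [load_table2()] for
#'   counting).
#' @return A list of class `metrics_report`: `k`, `me`, `sigma_e`,
#'   `mpe`, `mpe_sd`, `mae`, `rmse`, plus the paired table.
#' @examples
#' validate_counting()
#' @export
validate_counting <- function(reference = NULL, estimates = NULL) {
  if (is.null(reference)) reference <- load_table1()$views
  if (is.null(estimates)) estimates <- load_table2()
  m <- pair_views(reference, estimates, "n_visible", "n_est")
  out <- metrics_summary(m$n_est, m$n_visible)
  out$task <- "counting"
  out$pairs <- m
  out <- with_provenance(out, config = list(task = "counting"))
  class(out) <- "metrics_report"
  out
}

#' @rdname validate_counting
#' @export
validate_radius <- function(reference, estimates) {
  m <- pair_views(reference, estimates, "r_mean_px", "r_mean_est_px")
  out <- metrics_summary(m$r_mean_est_px, m$r_mean_px)
  out$task <- "radius"
  out$pairs <- m
  out <- with_provenance(out, config = list(task = "radius"))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s validation over K = %d views\n", x$task, x$k))
  cat(sprintf("  ME   = %8.4f (sd %.4f)\n", x$me, x$sigma_e))
  cat(sprintf("  MPE  = %7.3f%% (sd %.3f%%)\n", x$mpe, x$mpe_sd))
  cat(sprintf("  MAE  = %8.4f\n  RMSE = %8.4f\n", x$mae, x$rmse))
  invisible(x)
}

#' One row of the multi-cluster extrapolation table
#'
#' Convenience wrapper around [extrapolated_metrics()] that returns the
#' four table entries — extrapolated ME, MAE, normalized MAE and RMSE —
#' as a one-row data frame, full precision alongside display rounding.
#'
#' @param me,sigma_e Single-cluster error model, berries.
#' @param b Clusters per image.
#' @param berries_per_cluster Reference berries per cluster (default 50).
#' @return A one-row data frame: `me_b`, `mae_b`, `mae_norm_pct`,
#'   `rmse_b`, and `b`.
#' @examples
#' counting_extrapolation_row(-1.57, 1.9, 14)
#' @export
counting_extrapolation_row <- function(me, sigma_e, b,
                                       berries_per_cluster = 50) {
  m <- extrapolated_metrics(error_model(me, sigma_e), b,
                            berries_per_cluster)
  out <- data.frame(b = m$b, me_b = m$me_b, mae_b = m$mae_b,
                    mae_norm_pct = m$mae_norm, rmse_b = m$rmse_b)
  with_provenance(out, config = list(me = me, sigma_e = sigma_e, b = b,
                                     berries_per_cluster =
                                       berries_per_cluster))
}

#' Per-view bunch-volume error report
#'
#' Given estimated and reference whole-bunch volumes with a combined
#' standard uncertainty per view, reports the signed error
#' `E_k = v_est - v_ref`, the `k`-sigma compatibility flag, and the
#' summary coefficient of variability of the estimates per bunch.
#'
#' @param views A data frame with columns `bunch_id`, `view_index`,
#'   `v_est_mm`, `v_ref_mm`, `sigma_mm` (all volumes mm^3, sigma > 0).
#' @param k Coverage factor (default 2, ~95% under normality).
#' @return A list of class `volume_report`: the augmented per-view table
#'   (`error_mm`, `compatible`), `coverage`, `me`, `mpe`, `mean_cov`.
#' @export
volume_error_report <- function(views, k = 2) {
  needed <- c("bunch_id", "view_index", "v_est_mm", "v_ref_mm", "sigma_mm")
  missing <- setdiff(needed, names(views))
  if (length(missing))
    stop("volume report schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  u_est <- attr(views$v_est_mm, "unit"); u_ref <- attr(views$v_ref_mm, "unit")
  if ((!is.null(u_est) && u_est != "mm3") ||
      (!is.null(u_ref) && u_ref != "mm3"))
    stop("volume report requires mm^3 volumes; convert units first")
  views$error_mm <- views$v_est_mm - views$v_ref_mm
  views$compatible <- compatibility_check(views$error_mm, views$sigma_mm, k)
  per_bunch <- vapply(split(views$v_est_mm, views$bunch_id),
                      function(x) if (length(x) >= 2L)
                        coefficient_of_variability(x) else NA_real_,
                      numeric(1))
  out <- list(views = views,
              coverage = mean(views$compatible),
              me = mean_error(views$v_est_mm, views$v_ref_mm),
              mpe = mean_percentage_error(views$v_est_mm, views$v_ref_mm),
              mean_cov = mean(per_bunch, na.rm = TRUE),
              k = k)
  out <- with_provenance(out, config = list(k = k))
  class(out) <- "volume_report"
  out
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("bunch volume errors over %d views\n", nrow(x$views)))
  cat(sprintf("  ME = %.4g mm^3, MPE = %.3g%%, mean CoV = %.3g%%\n",
              x$me, x$mpe, x$mean_cov))
  cat(sprintf("  %.1f%% of views compatible at k = %g\n",
              100 * x$coverage, x$k))
  invisible(x)
}

#' Tabulate an uncertainty budget
#'
#' Formats an [propagate_power_product()] (or [monte_carlo_budget()])
#' result as a data frame with one row per source: nominal value,
#' standard uncertainty, exponent and UPC (percent of the combined
#' variance).
#'
#' @param budget An `uncertainty_budget`.
#' @return A data frame with attributes `combined_sigma` and `rel_sigma`.
#' @export
uncertainty_budget_report <- function(budget) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  out <- data.frame(source = budget$sources$name,
                    value = budget$sources$value,
                    sigma = budget$sources$sigma,
                    exponent = budget$sources$exponent,
                    upc_pct = unname(budget$upc))
  attr(out, "combined_sigma") <- budget$combined_sigma
  attr(out, "rel_sigma") <- budget$rel_sigma
  with_provenance(out, config = list())
}

#' Plot per-view volume errors with uncertainty bars
#'
#' Base-graphics error-bar chart of the signed volume errors of a
#' [volume_error_report()] (or a [run_recovery_experiment()] report),
#' with the +/- k sigma compatibility band.
#'
#' @param report A `volume_report` or `recovery_report`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_volume_errors <- function(report, ...) {
  v <- report$views
  err <- if ("error_mm" %in% names(v)) v$error_mm else v$v_est_mm - v$v_ref_mm
  sig <- v$sigma_mm
  idx <- seq_along(err)
  plot(idx, err, pch = 19, xlab = "view", ylab = "volume error (mm^3)",
       ylim = range(c(err - 2 * sig, err + 2 * sig), finite = TRUE), ...)
  graphics::arrows(idx, err - report$k * sig, idx, err + report$k * sig,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  graphics::abline(h = 0, lty = 2, col = "red")
  invisible(data.frame(idx, err, sig))
}
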