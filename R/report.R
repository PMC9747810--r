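#' End-to-end MCSE report from a sweep
#'
#' Runs the full analysis stage on a completed sweep: fits the loss curve,
#' estimates the MCSE with its error band, locates the AUC inflection
#' (when AUC was recorded), computes the pre/post-MCSE correlation report,
#' fits the post-MCSE extrapolation, and (when `target_auc` is given)
#' inverts it to a required sample size.
#'
#' An ill-defined MCSE is a finding, not a failure: the report is still
#' produced with `well_defined = FALSE` and the downstream stages are
#' skipped with `NULL` entries.
#'
#' @param sweep An `mcse_sweep`.
#' @param target_auc Optional desired test AUC in (0.5, 1).
#' @param kappa Well-definedness threshold passed to [estimate_mcse()].
#' @return An object of class `mcse_report`: a list with elements
#'   `aggregate`, `estimate`, `auc_inflection`, `correlation`,
#'   `extrapolation`, `requirement`.
#' @export
mcse_report <- function(sweep, target_auc = NULL, kappa = 3) {
  agg <- aggregate_sweep(sweep)
  have_auc <- any(is.finite(agg$auc_mean))
  est <- estimate_mcse(sweep, kappa = kappa)

  auc_infl <- NULL; corr <- NULL; extra <- NULL; req <- NULL
  if (have_auc) {
    auc_infl <- tryCatch(estimate_auc_inflection(sweep, kappa = kappa),
                         error = function(e) NULL)
    corr <- split_and_correlate(sweep, est)
    if (est$well_defined) {
      extra <- tryCatch(fit_extrapolation(sweep, est),
                        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(extra) && extra$valid && !is.null(target_auc)) {
        req <- required_sample_size(extra, est$curve, target_auc)
      }
    }
  }
  structure(list(aggregate = agg, estimate = est, auc_inflection = auc_infl,
                 correlation = corr, extrapolation = extra,
                 requirement = req, target_auc = target_auc),
            class = "mcse_report")
}

#' @export
print.mcse_report <- function(x, ...) {
  cat("== MCSE report ==\n")
  print(x$estimate)
  if (!is.null(x$auc_inflection)) print(x$auc_inflection)
  if (!is.null(x$correlation)) {
    cat("Correlation (replicate-level AUC vs -loss):\n")
    print(as_tibble(x$correlation))
  }
  if (!is.null(x$extrapolation)) print(x$extrapolation)
  if (!is.null(x$requirement)) {
    cat("Required sample size:\n")
    print(x$requirement)
  }
  invisible(x)
}

#' Serialise an MCSE report to JSON
#'
#' Writes every stage of the report (estimate, band, correlations,
#' extrapolation, requirement) plus the package version in one JSON
#' document.
#'
#' @param report An [mcse_report()].
#' @param path Output path.
#' @param config Optional run-configuration list echoed into the document.
#' @return `path`, invisibly.
#' @export
write_mcse_report <- function(report, path, config = NULL) {
  est <- report$estimate
  doc <- list(
    package_version = as.character(utils::packageVersion("mcse")),
    config = config,
    mcse = list(
      mcse_n = est$mcse_n, mcse_log2 = est$mcse_log2,
      loss_at_mcse = est$loss_at_mcse,
      band_n = est$band_n, band_loss = est$band_loss,
      curvature_peak = est$curvature_peak,
      well_defined = est$well_defined
    ),
    auc_inflection = if (!is.null(report$auc_inflection))
      list(n = report$auc_inflection$n,
           log2_n = report$auc_inflection$log2_n,
           well_defined = report$auc_inflection$well_defined),
    correlation = if (!is.null(report$correlation))
      as.data.frame(report$correlation),
    extrapolation = if (!is.null(report$extrapolation))
      as.data.frame(glance(report$extrapolation)),
    requirement = if (!is.null(report$requirement))
      as.data.frame(report$requirement),
    aggregate = as.data.frame(report$aggregate)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  invisible(path)
}

#' Render a wide correlation table across a simulation grid
#'
#' Binds several [split_and_correlate()] reports into one table shaped
#' like the simulation-study summaries: one row per grid configuration,
#' pre/post columns for each coefficient.
#'
#' @param reports Named list of `mcse_correlation` objects; names become
#'   the `value` column.
#' @param parameter Optional label for the varied parameter.
#' @return A tibble with columns `parameter`, `value`, `pre_r2`,
#'   `pre_kendall_tau`, `pre_spearman_rho`, `post_r2`, `post_kendall_tau`,
#'   `post_spearman_rho`.
#' @export
correlation_table <- function(reports, parameter = "value") {
  stopifnot(is.list(reports), length(reports) > 0,
            !is.null(names(reports)))
  purrr::imap(reports, function(rep, nm) {
    wide <- as_tibble(rep) |>
      dplyr::select("side", "r2", "kendall_tau", "spearman_rho") |>
      tidyr::pivot_wider(names_from = "side",
                         values_from = c("r2", "kendall_tau", "spearman_rho"),
                         names_glue = "{side}_{.value}")
    dplyr::bind_cols(tibble(parameter = parameter, value = nm), wide)
  }) |>
    dplyr::bind_rows()
}
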