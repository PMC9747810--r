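#' Pre/post-MCSE correlation between classifier AUC and autoencoder loss
#'
#' Partitions the replicate-level `(auc, loss)` pairs of a sweep at the
#' MCSE (`n < mcse_n` vs `n >= mcse_n`) and reports, for each side, the
#' squared Pearson correlation plus Kendall's tau and Spearman's rho. Loss
#' is negated in every pairing, so all three coefficients are positive
#' when higher AUC accompanies lower loss. Below a real learning
#' transition the two quantities should be uncorrelated; above it they
#' should correlate strongly.
#'
#' Sides with fewer than 3 points, or with degenerate variance in either
#' variable, get `NA` coefficients (undefined, not zero).
#'
#' @param sweep An `mcse_sweep` with both `auc` and `loss` recorded.
#' @param mcse An `mcse_estimate`, or a single sample size to split at.
#' @return A tibble of class `mcse_correlation` with one row per side
#'   (`pre`, `post`) and columns `n_points`, `r2`, `kendall_tau`,
#'   `spearman_rho`; the split point is attached as attribute `"split_n"`.
#' @export
split_and_correlate <- function(sweep, mcse) {
  stopifnot(is.data.frame(sweep), all(c("n", "auc", "loss") %in% names(sweep)))
  split_n <- if (inherits(mcse, "mcse_estimate")) mcse$mcse_n
             else check_number(mcse, "mcse", min = 0)
  pts <- as_tibble(sweep) |>
    dplyr::filter(is.finite(.data$auc), is.finite(.data$loss))

  side_stats <- function(d) {
    out <- tibble(n_points = nrow(d), r2 = NA_real_,
                  kendall_tau = NA_real_, spearman_rho = NA_real_)
    if (nrow(d) < 3) return(out)
    if (sd(d$auc) < 1e-12 || sd(d$loss) < 1e-12) return(out)
    out$r2 <- cor(d$auc, -d$loss)^2
    out$kendall_tau <- cor(d$auc, -d$loss, method = "kendall")
    out$spearman_rho <- cor(d$auc, -d$loss, method = "spearman")
    out
  }

  out <- dplyr::bind_rows(
    dplyr::mutate(side_stats(dplyr::filter(pts, .data$n < split_n)),
                  side = "pre", .before = 1),
    dplyr::mutate(side_stats(dplyr::filter(pts, .data$n >= split_n)),
                  side = "post", .before = 1)
  )
  structure(out, split_n = split_n,
            class = c("mcse_correlation", class(tibble())))
}

#' Fit the post-MCSE AUC-vs-loss relation
#'
#' Above the MCSE the classifier's generalisation grows as the autoencoder
#' loss falls, with a scaling constant beta linking the two rates; its
#' integrated form is an affine relation `AUC = intercept + slope * loss`
#' with `slope = -beta`. This fits that relation by least squares to the
#' per-sample-size *means* of the post-MCSE segment (`n >= mcse_n`).
#'
#' A non-negative slope (AUC failing to improve as loss falls) flags the
#' fit invalid.
#'
#' @inheritParams split_and_correlate
#' @return An object of class `mcse_extrapolation` with fields `beta`,
#'   `intercept`, `slope`, `fit_r2`, `valid`, `domain` (the loss range the
#'   fit covers) and the underlying `lm` fit.
#' @export
fit_extrapolation <- function(sweep, mcse) {
  split_n <- if (inherits(mcse, "mcse_estimate")) mcse$mcse_n
             else check_number(mcse, "mcse", min = 0)
  agg <- aggregate_sweep(sweep) |>
    dplyr::filter(.data$n >= split_n, is.finite(.data$auc_mean),
                  is.finite(.data$loss_mean))
  if (nrow(agg) < 3)
    abort(sprintf("need >= 3 post-MCSE sample sizes for the extrapolation fit, have %d",
                  nrow(agg)))
  fit <- lm(auc_mean ~ loss_mean, data = agg)
  slope <- unname(coef(fit)[2])
  valid <- is.finite(slope) && slope < 0
  if (!valid)
    warn("slope >= 0: AUC is not improving as loss falls; extrapolation fit flagged invalid")
  structure(list(
    beta = -slope, intercept = unname(coef(fit)[1]), slope = slope,
    fit_r2 = summary(fit)$r.squared, valid = valid,
    domain = range(agg$loss_mean), split_n = split_n,
    n_points = nrow(agg), lm = fit
  ), class = "mcse_extrapolation")
}

#' @export
print.mcse_extrapolation <- function(x, ...) {
  cat(sprintf("<mcse_extrapolation> AUC = %.4f %+.4g * loss  (beta = %.4g)\n",
              x$intercept, x$slope, x$beta))
  cat(sprintf("  fit R^2 = %.3f over %d post-MCSE sizes, loss domain [%.4g, %.4g]%s\n",
              x$fit_r2, x$n_points, x$domain[1], x$domain[2],
              if (x$valid) "" else "  [INVALID]"))
  invisible(x)
}

#' @rdname fit_extrapolation
#' @param x An `mcse_extrapolation`.
#' @param ... Unused.
#' @export
tidy.mcse_extrapolation <- function(x, ...) {
  tibble(term = c("intercept", "slope", "beta"),
         estimate = c(x$intercept, x$slope, x$beta))
}

#' @rdname fit_extrapolation
#' @export
glance.mcse_extrapolation <- function(x, ...) {
  tibble(beta = x$beta, fit_r2 = x$fit_r2, valid = x$valid,
         n_points = x$n_points,
         loss_domain_lower = x$domain[1], loss_domain_upper = x$domain[2])
}

#' Sample size required for a target test AUC
#'
#' Inverts the post-MCSE extrapolation fit to the loss level that achieves
#' `target_auc`, then inverts the monotone-decreasing segment of the loss
#' curve to the corresponding sample size. Targets whose loss level lies
#' below the curve's observed floor are reported `unreachable` — the data
#' (or the network) cannot demonstrably support that performance within
#' the sampled range.
#'
#' @param fit A valid [fit_extrapolation()] result.
#' @param loss_curve The `mcse_curve` fitted to mean autoencoder loss.
#' @param target_auc Desired held-out macro AUC, strictly between 0.5
#'   (the non-trivial-classifier threshold) and 1.
#' @return A one-row tibble: `target_auc`, `loss_target`, `required_n`
#'   (`NA` when unreachable), `unreachable`.
#' @export
required_sample_size <- function(fit, loss_curve, target_auc) {
  stopifnot(inherits(fit, "mcse_extrapolation"),
            inherits(loss_curve, "mcse_curve"))
  target_auc <- check_number(target_auc, "target_auc")
  if (target_auc <= 0.5 || target_auc >= 1)
    abort("`target_auc` must lie strictly between 0.5 and 1")
  if (!fit$valid) abort("extrapolation fit is invalid (non-negative slope)")

  loss_target <- (target_auc - fit$intercept) / fit$slope

  grid <- seq(min(loss_curve$x), max(loss_curve$x), length.out = 4001)
  v <- predict(loss_curve, grid)
  # monotone-decreasing segment: from the global maximum down to the
  # global minimum of the smoothed curve
  i_hi <- which.max(v)
  i_lo <- which.min(v[i_hi:length(v)]) + i_hi - 1L
  seg <- i_hi:i_lo
  if (loss_target < min(v[seg])) {
    return(tibble(target_auc = target_auc, loss_target = loss_target,
                  required_n = NA_real_, unreachable = TRUE))
  }
  j <- seg[which(v[seg] <= loss_target)[1]] # smallest n reaching the level
  tibble(target_auc = target_auc, loss_target = loss_target,
         required_n = 2^grid[j], unreachable = FALSE)
}
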