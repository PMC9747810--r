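#' Fit a natural cubic spline to a learning curve
#'
#' Smooths a per-sample-size mean metric (autoencoder loss or classifier
#' AUC) with a natural cubic spline in `x = log2(n)`. The log2 axis matches
#' the doubling sweep design, making the knots equally spaced; derivatives
#' of the curve are therefore taken with respect to log2(n), where the
#' inflection structure of the two learning phases is visible. Natural
#' boundary conditions pin the second derivative to zero at the end knots.
#'
#' @param ns Strictly increasing sample sizes (at least 4).
#' @param values Finite metric means, one per sample size.
#' @return An object of class `mcse_curve` that can be evaluated (value,
#'   first and second derivative) at any `log2(n)` within the fitted range
#'   via [predict.mcse_curve()].
#' @export
fit_learning_curve <- function(ns, values) {
  if (length(ns) != length(values)) abort("`ns` and `values` lengths differ")
  if (length(ns) < 4)
    abort("need at least 4 sample sizes to estimate curvature")
  if (any(!is.finite(ns)) || any(ns <= 0) || any(diff(ns) <= 0))
    abort("`ns` must be strictly increasing positive sample sizes")
  if (any(!is.finite(values))) abort("`values` must be finite")
  x <- log2(ns)
  structure(list(
    x = x, y = as.numeric(values), ns = as.numeric(ns),
    fun = splinefun(x, values, method = "natural")
  ), class = "mcse_curve")
}

#' Evaluate a fitted learning curve
#'
#' @param object An `mcse_curve`.
#' @param x Evaluation points on the `log2(n)` axis; must lie within the
#'   fitted knot range (extrapolation is refused).
#' @param deriv Derivative order: 0 (value), 1, or 2.
#' @param ... Unused.
#' @return Numeric vector of curve values or derivatives.
#' @export
predict.mcse_curve <- function(object, x, deriv = 0, ...) {
  if (any(x < min(object$x) - 1e-9) || any(x > max(object$x) + 1e-9))
    abort(sprintf("evaluation outside the fitted range [%g, %g] on log2(n)",
                  min(object$x), max(object$x)))
  if (!deriv %in% 0:2) abort("`deriv` must be 0, 1 or 2")
  object$fun(x, deriv = deriv)
}

#' @export
print.mcse_curve <- function(x, ...) {
  cat(sprintf("<mcse_curve> natural spline on %d knots, n in [%g, %g]\n",
              length(x$x), min(x$ns), max(x$ns)))
  invisible(x)
}

# Shared inflection machinery: argmax of (sign * second derivative) over a
# dense interior grid. The outermost half knot spacing on each side is
# excluded because natural boundary conditions force the curvature to zero
# there by construction, not by data.
#' @keywords internal
locate_inflection <- function(curve, sign = 1, grid_size = 2001, kappa = 3) {
  stopifnot(inherits(curve, "mcse_curve"))
  h <- stats::median(diff(curve$x))
  lo <- min(curve$x) + h / 2
  hi <- max(curve$x) - h / 2
  grid <- seq(lo, hi, length.out = grid_size)
  d2 <- predict(curve, grid, deriv = 2)
  i <- which.max(sign * d2) # first maximum: ties break to the smallest n
  peak <- sign * d2[i]

  # noise floor: the peak must stand out from the typical curvature
  # magnitude over the grid (a sharp inflection concentrates curvature; a
  # noise-dominated spline wiggles with comparable |d2| everywhere), and
  # must exceed an absolute floor so flat/linear curves (zero curvature up
  # to round-off) are never declared inflections
  spread <- stats::median(abs(d2))
  scale_floor <- 1e-8 * (diff(range(curve$y)) + 1e-300) / h^2
  well_defined <- is.finite(peak) && peak > max(kappa * spread, scale_floor)

  list(log2_n = grid[i], n = 2^grid[i], peak = peak,
       well_defined = well_defined, grid_step = diff(grid[1:2]))
}

#' Estimate the minimum convergence sample from a loss curve
#'
#' The MCSE is the sample size at the inflection of the autoencoder
#' reconstruction-loss curve: the maximiser of the curve's second
#' derivative, located on a dense grid over the interior of the fitted
#' spline. The estimate is flagged `well_defined = FALSE` when the
#' curvature peak does not stand out from the curve's curvature noise floor
#' (peak below `kappa` times the median of |d2| over the grid) — the
#' behaviour expected of unstructured data, where no learning
#' transition exists. The error band evaluates the loss curve at
#' `exp(ln(MCSE) - 1)` and `exp(ln(MCSE) + 1)` (i.e. MCSE/e and MCSE*e),
#' clipped to the sampled range.
#'
#' @param loss_curve An `mcse_curve` fitted to mean reconstruction loss,
#'   or an `mcse_sweep` (the loss curve is then fitted internally).
#' @param grid_size Number of evaluation points for the argmax search.
#' @param kappa Well-definedness threshold: the curvature peak must exceed
#'   `kappa` times the median absolute curvature over the grid.
#' @return An object of class `mcse_estimate` with fields `mcse_n`,
#'   `mcse_log2`, `loss_at_mcse`, `band_n`, `band_loss`, `curvature_peak`,
#'   `well_defined` and the fitted `curve`.
#' @export
estimate_mcse <- function(loss_curve, grid_size = 2001, kappa = 3) {
  if (inherits(loss_curve, "mcse_sweep") ||
      (is.data.frame(loss_curve) && all(c("n", "loss") %in% names(loss_curve)))) {
    agg <- aggregate_sweep(loss_curve)
    loss_curve <- fit_learning_curve(agg$n, agg$loss_mean)
  }
  loc <- locate_inflection(loss_curve, sign = 1, grid_size = grid_size,
                           kappa = kappa)
  band_n <- pmin(pmax(loc$n * exp(c(-1, 1)), min(loss_curve$ns)),
                 max(loss_curve$ns))
  structure(list(
    mcse_n = loc$n, mcse_log2 = loc$log2_n,
    loss_at_mcse = predict(loss_curve, loc$log2_n),
    band_n = band_n,
    band_loss = predict(loss_curve, log2(band_n)),
    curvature_peak = loc$peak, well_defined = loc$well_defined,
    grid_step = loc$grid_step, kappa = kappa,
    curve = loss_curve
  ), class = "mcse_estimate")
}

#' Locate the inflection of an AUC learning curve
#'
#' The AUC curve mirrors the loss curve, so its inflection is the
#' *minimiser* of the second derivative (the point of sharpest transition
#' from the rapid-growth to the slow-growth phase). Used to validate that
#' the classifier's own learning transition occurs at a similar sample
#' size to the autoencoder-derived MCSE.
#'
#' @param auc_curve An `mcse_curve` fitted to mean test AUC, or an
#'   `mcse_sweep`.
#' @inheritParams estimate_mcse
#' @return An object of class `mcse_inflection` with fields `n`, `log2_n`,
#'   `curvature_peak` (magnitude of the extremal curvature) and
#'   `well_defined`.
#' @export
estimate_auc_inflection <- function(auc_curve, grid_size = 2001, kappa = 3) {
  if (inherits(auc_curve, "mcse_sweep") ||
      (is.data.frame(auc_curve) && all(c("n", "auc") %in% names(auc_curve)))) {
    agg <- aggregate_sweep(auc_curve)
    auc_curve <- fit_learning_curve(agg$n, agg$auc_mean)
  }
  loc <- locate_inflection(auc_curve, sign = -1, grid_size = grid_size,
                           kappa = kappa)
  structure(list(n = loc$n, log2_n = loc$log2_n, curvature_peak = loc$peak,
                 well_defined = loc$well_defined, curve = auc_curve),
            class = "mcse_inflection")
}

#' @export
print.mcse_estimate <- function(x, ...) {
  cat("<mcse_estimate>\n")
  if (x$well_defined) {
    cat(sprintf("  MCSE: n = %.0f (log2 = %.2f), loss %.4g\n",
                x$mcse_n, x$mcse_log2, x$loss_at_mcse))
    cat(sprintf("  band: n in [%.0f, %.0f], loss in [%.4g, %.4g]\n",
                x$band_n[1], x$band_n[2], x$band_loss[1], x$band_loss[2]))
  } else {
    cat(sprintf("  NOT well defined (curvature peak %.3g below the noise floor)\n",
                x$curvature_peak))
    cat(sprintf("  nominal argmax at n = %.0f\n", x$mcse_n))
  }
  invisible(x)
}

#' @export
print.mcse_inflection <- function(x, ...) {
  cat(sprintf("<mcse_inflection> AUC inflection at n = %.0f (log2 = %.2f)%s\n",
              x$n, x$log2_n,
              if (x$well_defined) "" else " [not well defined]"))
  invisible(x)
}

#' @rdname estimate_mcse
#' @param x An `mcse_estimate`.
#' @param ... Unused.
#' @export
tidy.mcse_estimate <- function(x, ...) {
  tibble(
    mcse_n = x$mcse_n, mcse_log2 = x$mcse_log2,
    loss_at_mcse = x$loss_at_mcse,
    band_n_lower = x$band_n[1], band_n_upper = x$band_n[2],
    band_loss_lower = x$band_loss[1], band_loss_upper = x$band_loss[2],
    curvature_peak = x$curvature_peak, well_defined = x$well_defined
  )
}

#' @rdname estimate_mcse
#' @export
glance.mcse_estimate <- function(x, ...) {
  tibble(mcse_n = x$mcse_n, well_defined = x$well_defined,
         n_knots = length(x$curve$x),
         n_range_lower = min(x$curve$ns), n_range_upper = max(x$curve$ns))
}
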