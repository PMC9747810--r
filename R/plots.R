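#' Plot the paired learning curves of a sweep
#'
#' Replicate-level points and per-size means for classifier AUC and
#' autoencoder reconstruction loss against log2(sample size).
#'
#' @param object An `mcse_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcse_sweep <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("auc", "loss"), names_to = "metric") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         auc = "classifier test AUC",
                                         loss = "autoencoder test loss"))
  means <- long |>
    dplyr::group_by(.data$metric, .data$n) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = log2(.data$n), y = .data$value)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = means, colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "log2(sample size)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a loss curve with its MCSE and error band
#'
#' Three panels — the smoothed loss curve and its first and second
#' derivatives on the log2(n) axis — with a vertical line at the MCSE and
#' the loss error band (MCSE/e to MCSE*e) shaded.
#'
#' @param object An `mcse_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcse_estimate <- function(object, ...) {
  curve <- object$curve
  grid <- seq(min(curve$x), max(curve$x), length.out = 400)
  dat <- dplyr::bind_rows(
    tibble(x = grid, y = predict(curve, grid), panel = "loss"),
    tibble(x = grid, y = predict(curve, grid, deriv = 1), panel = "d loss / d log2(n)"),
    tibble(x = grid, y = predict(curve, grid, deriv = 2), panel = "d2 loss / d log2(n)2")
  ) |>
    dplyr::mutate(panel = factor(.data$panel, unique(.data$panel)))
  knots <- tibble(x = curve$x, y = curve$y, panel = factor("loss", levels(dat$panel)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("rect", xmin = log2(object$band_n[1]),
                      xmax = log2(object$band_n[2]), ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = knots, size = 1.4) +
    ggplot2::geom_vline(xintercept = object$mcse_log2, linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "log2(sample size)", y = NULL,
                  subtitle = if (object$well_defined)
                    sprintf("MCSE = %.0f samples", object$mcse_n)
                  else "MCSE not well defined") +
    ggplot2::theme_minimal()
  p
}

#' Plot the post-MCSE AUC-vs-loss extrapolation
#'
#' Per-size mean AUC against mean loss with the fitted affine relation;
#' points below the MCSE are shown hollow.
#'
#' @param object An `mcse_extrapolation`.
#' @param sweep The `mcse_sweep` the fit came from (for the points).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcse_extrapolation <- function(object, sweep, ...) {
  agg <- aggregate_sweep(sweep) |>
    dplyr::mutate(side = ifelse(.data$n >= object$split_n, "post", "pre"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$loss_mean, y = .data$auc_mean)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2, colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$side), size = 2) +
    ggplot2::scale_shape_manual(values = c(pre = 1, post = 16)) +
    ggplot2::labs(x = "mean autoencoder test loss",
                  y = "mean classifier test AUC", shape = NULL,
                  subtitle = sprintf("beta = %.3g, fit R2 = %.3f",
                                     object$beta, object$fit_r2)) +
    ggplot2::theme_minimal()
}
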