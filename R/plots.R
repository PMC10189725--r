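#' Plot a dimensionless uptake curve
#'
#' Log-log plot of the uptake rate `dM/dT` against dimensionless time, in
#' the style used to compare simulated curves with their limiting regimes.
#' Closed-form limits can be overlaid for the curve's own `z_ratio`.
#'
#' @param object A `dimless_curve` from [simulate_uptake()] or
#'   [simulate_1d()].
#' @param limits Limiting-regime curves to overlay (see [limit_curves()]),
#'   or `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dimless_curve
#' @export
autoplot.dimless_curve <- function(object, limits = c("shoup_szabo", "cylinder"), ...) {
  z <- attr(object, "z_ratio")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$T, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "dimensionless time T",
      y = "dimensionless uptake rate dM/dT",
      title = sprintf("Simulated uptake rate, z_ratio = %.3g (%s)",
                      z, attr(object, "mode")))
  if (!is.null(limits) && length(limits)) {
    lc <- limit_curves(z, t_min = min(object$T), t_max = max(object$T),
                       n = 200, which = limits)
    p <- p + ggplot2::geom_line(
      data = lc,
      ggplot2::aes(x = .data$T, y = .data$rate, colour = .data$curve),
      linetype = "dashed") +
      ggplot2::labs(colour = "limiting regime")
  }
  p
}

#' Plot an uptake fit
#'
#' Observed leaf-extract masses against time with the fitted model curve,
#' on a log time axis (zero-time observations are shown at the smallest
#' positive time).
#'
#' @param object An `uptake_fit` from [fit_uptake()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uptake_fit
#' @export
autoplot.uptake_fit <- function(object, ...) {
  d <- object$data
  tmin <- min(d$time_min[d$time_min > 0])
  dd <- dplyr::mutate(d, time_plot = pmax(.data$time_min, tmin / 2))
  curve <- dplyr::arrange(dd, .data$time_plot)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$time_plot)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mass_TL_ug), alpha = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$fitted_ug), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time since application (min)",
                  y = "leaf-extract mass (µg)",
                  title = sprintf("Uptake fit: R² = %.3f", object$r_squared))
}
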