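#' Plot an uncertainty band
#'
#' Ribbon of the 95% limits with the point-prediction curve.
#'
#' @param object An `n2o_band`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot n2o_band
#' @export
autoplot.n2o_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point)) +
    ggplot2::labs(
      x = "Applied N (kg N ha⁻¹)",
      y = expression(N[2] * O ~ emission ~ (kg ~ N ~ ha^-1 ~ yr^-1)),
      title = object$model[1]
    )
}

#' Plot an ensemble uncertainty range against the IPCC-Tier 1 range
#'
#' Dark ribbon: full best-case/worst-case range (equations + parameters);
#' light ribbon: equation range (member point predictions). Optionally
#' overlays the Tier 1 line (EF 1%) and its 0.3-3% uncertainty range.
#'
#' @param object An `n2o_ensemble` from [ensemble_range()].
#' @param show_ipcc Overlay the IPCC-Tier 1 line and range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot n2o_ensemble
#' @export
autoplot.n2o_ensemble <- function(object, show_ipcc = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey55", alpha = 0.7) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eq_low, ymax = .data$eq_high),
                         fill = "grey85", alpha = 0.9) +
    ggplot2::labs(
      x = "Applied N (kg N ha⁻¹)",
      y = expression(N[2] * O ~ emission ~ due ~ to ~ N ~ (kg ~ N ~ ha^-1 ~ yr^-1))
    )
  if (show_ipcc) {
    ipcc <- ipcc_range(object$dose)
    p <- p +
      ggplot2::geom_line(data = ipcc, ggplot2::aes(y = .data$point)) +
      ggplot2::geom_line(data = ipcc, ggplot2::aes(y = .data$low),
                         linetype = "dotted") +
      ggplot2::geom_line(data = ipcc, ggplot2::aes(y = .data$high),
                         linetype = "dotted")
  }
  p
}

#' Fitted response curves for several models
#'
#' Population-level mean response of each fitted model over a dose grid,
#' optionally over the observed data points.
#'
#' @param fits List of `n2o_fit` objects.
#' @param data Optional emission tibble to draw as points.
#' @param dose_grid Dose grid, kg N ha^-1.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(fits, data = NULL,
                                 dose_grid = seq(0, 500, by = 5)) {
  curves <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$spec$name, dose = dose_grid,
                   emission = mean_response(f$spec, f$estimates, dose_grid))
  })
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$dose, y = .data$emission,
                                    colour = .data$model))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(dose = data$n_rate_kg_ha,
                            emission = data$n2o_kg_n_ha_yr),
      ggplot2::aes(x = .data$dose, y = .data$emission),
      inherit.aes = FALSE, alpha = 0.3, size = 0.8
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(
      x = "Applied N (kg N ha⁻¹)",
      y = expression(N[2] * O ~ emission ~ (kg ~ N ~ ha^-1 ~ yr^-1)),
      colour = "Model"
    )
}
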