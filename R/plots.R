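#' Plot desorption isotherms with fitted curves
#'
#' Scatter of measured EMC against water activity, faceted by product, with
#' the fitted isotherms overlaid per temperature when a fit is supplied.
#'
#' @param data Isotherm records.
#' @param fit Optional `sorption_fit` whose isotherms to overlay.
#' @param emc_range Moisture span for the overlay curves.
#' @return A ggplot object.
#' @export
plot_isotherms <- function(data, fit = NULL, emc_range = NULL) {
  data <- validate_isotherms(data, require_design = TRUE)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$erh, y = .data$emc,
                                          colour = factor(.data$temp_c))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~product) +
    ggplot2::labs(x = "Equilibrium relative humidity (decimal)",
                  y = "EMC (kg/kg db)", colour = "Temp (degC)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    if (is.null(emc_range)) emc_range <- range(data$emc)
    grid <- tidyr::expand_grid(
      emc = seq(emc_range[1], emc_range[2], length.out = 100),
      temp_c = sort(unique(data$temp_c))
    )
    grid$erh <- predict_erh(fit$spec, grid$emc, grid$temp_c)
    p <- p + ggplot2::geom_path(
      data = grid,
      ggplot2::aes(x = .data$erh, y = .data$emc,
                   colour = factor(.data$temp_c)),
      inherit.aes = FALSE, linewidth = 0.4)
  }
  p
}

#' @rdname thermo_curves
#' @param object A `thermo_curve`.
#' @export
autoplot.thermo_curve <- function(object, which = c("curve", "surface"), ...) {
  which <- match.arg(which)
  if (which == "curve") {
    long <- tidyr::pivot_longer(object$curve, c("dH", "dS"),
                                names_to = "quantity", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$emc, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~quantity, scales = "free_y") +
      ggplot2::labs(x = "EMC (kg/kg db)",
                    y = "dH (J/mol) / dS (J/(mol K))",
                    title = paste("Differential enthalpy and entropy:",
                                  object$spec$family)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$surface,
                    ggplot2::aes(x = .data$emc, y = .data$qst_kj_kg,
                                 colour = factor(.data$temp_c))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "EMC (kg/kg db)", y = "Net isosteric heat (kJ/kg)",
                    colour = "Temp (degC)",
                    title = paste("Temperature dependence of qst:",
                                  object$spec$family)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname krug_test
#' @export
autoplot.compensation_result <- function(object, ...) {
  pairs <- attr(object, "pairs")
  if (is.null(pairs)) {
    stop("no (dH, dS) pairs stored; run compensation_analysis()", call. = FALSE)
  }
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$dS, y = .data$dH)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "black") +
    ggplot2::labs(x = "dS (J/(mol K))", y = "dH (J/mol)",
                  title = sprintf("Compensation line: T_beta = %.0f K, T_hm = %.0f K (%s)",
                                  object$T_beta, object$T_hm, object$control)) +
    ggplot2::theme_minimal()
}

#' Plot a dryer energy-efficiency profile
#'
#' @param profile Output of [efficiency_profile()].
#' @return A ggplot object with drying rate and efficiency panels.
#' @export
plot_efficiency_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    dplyr::transmute(profile, t = (.data$t_start + .data$t_end) / 2,
                     `drying rate (kg/h)` = .data$m_w,
                     `efficiency` = .data$eta),
    -"t", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
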