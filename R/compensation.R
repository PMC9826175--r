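#' Harmonic mean of experimental temperatures
#'
#' `T_hm = n / sum(1 / Tabs_i)` on the absolute (kelvin) scale. The Krug
#' procedure compares the isokinetic temperature against this quantity: a
#' compensation line fitted through estimated (dH, dS) pairs is only
#' meaningful when its slope is statistically distinct from `T_hm`.
#'
#' @param temps Temperatures in degrees Celsius (non-empty, above absolute
#'   zero).
#' @return Harmonic mean temperature in kelvin.
#' @export
#' @examples
#' harmonic_mean_temperature(seq(25, 65, 10)) # ~317.5 K
harmonic_mean_temperature <- function(temps) {
  if (length(temps) == 0) stop("temps must be non-empty", call. = FALSE)
  if (any(temps <= -.K0)) stop("temperatures below absolute zero", call. = FALSE)
  length(temps) / sum(1 / (temps + .K0))
}

#' Isokinetic (compensation) regression
#'
#' Ordinary least-squares regression of differential enthalpy on
#' differential entropy across moisture levels, `dH = T_beta * dS + dG_beta`.
#' The slope is the isokinetic temperature `T_beta` (K), the intercept the
#' Gibbs free energy `dG_beta` (J/mol) at that temperature. The 95 percent
#' confidence interval for `T_beta` is the usual t-interval on the slope.
#'
#' @param pairs Data frame with columns `dH` (J/mol) and `dS` (J/(mol K));
#'   at least 3 rows with non-degenerate `dS` spread.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return One-row tibble: `T_beta`, `dG_beta`, `slope_se`, `T_beta_lower`,
#'   `T_beta_upper`, `n_points`.
#' @export
isokinetic_regression <- function(pairs, conf_level = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("dH", "dS") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 (dH, dS) pairs", call. = FALSE)
  if (stats::sd(pairs$dS) == 0) {
    stop("zero variance in dS; isokinetic regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(dH ~ dS, data = pairs)
  # pairs derived from one parametric isotherm are near-exactly collinear;
  # summary.lm's perfect-fit warning is expected structure there
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["dS", "Estimate"]
  se <- cf["dS", "Std. Error"]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  tibble::tibble(
    T_beta = slope,
    dG_beta = cf["(Intercept)", "Estimate"],
    slope_se = se,
    T_beta_lower = slope - tcrit * se,
    T_beta_upper = slope + tcrit * se,
    n_points = n
  )
}

#' Krug test of enthalpy-entropy compensation
#'
#' Classifies the process by where the harmonic mean temperature falls
#' relative to the confidence interval of the isokinetic temperature:
#' compensation is statistically valid only when `T_hm` lies outside the
#' interval; the process is enthalpy-controlled when `T_beta > T_hm`
#' (interval entirely above `T_hm`) and entropy-controlled when
#' `T_beta < T_hm`.
#'
#' @param reg Output of [isokinetic_regression()].
#' @param T_hm Harmonic mean temperature in kelvin.
#' @return Object of class `compensation_result`.
#' @export
krug_test <- function(reg, T_hm) {
  stopifnot(is.data.frame(reg), nrow(reg) == 1)
  valid <- T_hm < reg$T_beta_lower || T_hm > reg$T_beta_upper
  control <- if (T_hm < reg$T_beta_lower) {
    "enthalpy_controlled"
  } else if (T_hm > reg$T_beta_upper) {
    "entropy_controlled"
  } else {
    "inconclusive"
  }
  structure(list(
    T_beta = reg$T_beta,
    T_beta_ci = c(reg$T_beta_lower, reg$T_beta_upper),
    dG_beta = reg$dG_beta,
    T_hm = T_hm,
    compensation_valid = valid,
    control = control,
    n_points = reg$n_points
  ), class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("<compensation_result>\n")
  cat(sprintf("  T_beta = %.1f K (95%% CI %.1f - %.1f), T_hm = %.1f K\n",
              x$T_beta, x$T_beta_ci[1], x$T_beta_ci[2], x$T_hm))
  cat(sprintf("  dG_beta = %.3g J/mol | compensation %s | %s\n",
              x$dG_beta, if (x$compensation_valid) "valid" else "not established",
              x$control))
  if (abs(x$dG_beta) < 500) {
    cat("  near-zero dG_beta: system would be in equilibrium at the isokinetic temperature\n")
  }
  invisible(x)
}

#' @rdname krug_test
#' @param x A `compensation_result`.
#' @param ... Unused.
#' @export
tidy.compensation_result <- function(x, ...) {
  tibble::tibble(
    T_beta = x$T_beta,
    T_beta_lower = x$T_beta_ci[1],
    T_beta_upper = x$T_beta_ci[2],
    dG_beta = x$dG_beta,
    T_hm = x$T_hm,
    compensation_valid = x$compensation_valid,
    control = x$control,
    n_points = x$n_points
  )
}

#' @rdname krug_test
#' @param object A `compensation_result`.
#' @export
glance.compensation_result <- function(object, ...) tidy(object)

#' Full enthalpy-entropy compensation analysis for a sorption model
#'
#' Computes (dH, dS) pairs by van't Hoff regression over a moisture grid,
#' fits the isokinetic line and applies the Krug test against the harmonic
#' mean of the experimental temperatures. The default grid 0.06--0.28 kg/kg
#' covers the moisture span typical of cassava desorption experiments.
#'
#' @inheritParams predict_erh
#' @param emc_grid Moisture grid for the (dH, dS) pairs.
#' @param temps Experimental temperatures, degC.
#' @param conf_level Confidence level for the isokinetic slope.
#' @return A `compensation_result` (see [krug_test()]); the (dH, dS) pairs
#'   are kept in attribute `"pairs"`.
#' @export
#' @examples
#' compensation_analysis(reference_spec("chung_pfost"))
compensation_analysis <- function(spec, emc_grid = seq(0.06, 0.28, by = 0.01),
                                  temps = seq(25, 65, by = 10),
                                  conf_level = 0.95) {
  pairs <- purrr::map_dfr(emc_grid, vant_hoff_point, spec = spec,
                          temps = temps)
  reg <- isokinetic_regression(pairs[, c("dH", "dS")], conf_level = conf_level)
  out <- krug_test(reg, harmonic_mean_temperature(temps))
  attr(out, "pairs") <- pairs
  out
}
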