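#' Latent heat of vaporisation of pure water
#'
#' Linear interpolation anchored at 44.200 kJ/mol at 20 degC and
#' 42.030 kJ/mol at 70 degC (linearity of the latent heat over this span is
#' accurate to well under 0.2 percent). Extrapolates linearly over the rest
#' of 0--100 degC.
#'
#' @param temp_c Temperature in degrees Celsius, within `[0, 100]`.
#' @return Latent heat in J per mol of water.
#' @export
#' @examples
#' latent_heat_water(20) # 44200
#' latent_heat_water(45) # 43115
latent_heat_water <- function(temp_c) {
  if (any(temp_c < 0 | temp_c > 100)) {
    stop("temp_c must lie within [0, 100] degC", call. = FALSE)
  }
  44200 + (42030 - 44200) / (70 - 20) * (temp_c - 20)
}

#' Total isosteric heat of desorption
#'
#' `Qst = qst + Lv(T)`: the net isosteric heat from the sorption model plus
#' the latent heat of pure water at the same temperature.
#'
#' @inheritParams predict_erh
#' @return Total isosteric heat, J per mol water.
#' @export
total_isosteric_heat <- function(spec, emc, temp_c) {
  net_isosteric_heat(spec, emc, temp_c) + latent_heat_water(temp_c)
}

#' Differential enthalpy and entropy at one moisture content
#'
#' Van't Hoff analysis of a fitted sorption model: ordinary least-squares
#' regression of `ln(ERH)` on `1/Tabs` across the supplied temperatures at
#' fixed moisture content. The slope is `-dH/R` and the intercept `dS/R`,
#' giving the (temperature-averaged) differential enthalpy and entropy of
#' desorption at that moisture level.
#'
#' @inheritParams predict_erh
#' @param temps Temperatures in degC (at least two distinct values).
#' @return One-row tibble with `emc`, `dH` (J/mol) and `dS` (J/(mol K)).
#' @export
#' @examples
#' cp <- reference_spec("chung_pfost")
#' vant_hoff_point(cp, 0.25, seq(25, 65, 10))
vant_hoff_point <- function(spec, emc, temps) {
  if (length(unique(temps)) < 2) {
    stop("van't Hoff regression needs at least 2 distinct temperatures",
         call. = FALSE)
  }
  stopifnot(length(emc) == 1)
  inv_t <- 1 / (temps + .K0)
  ln_erh <- log(predict_erh(spec, emc, temps))
  cf <- stats::coef(stats::lm(ln_erh ~ inv_t))
  tibble::tibble(emc = emc,
                 dH = -.R_GAS * unname(cf[2]),
                 dS = .R_GAS * unname(cf[1]))
}

#' Thermodynamic curves from a fitted sorption model
#'
#' Derives, over a moisture-content grid, (i) the differential enthalpy and
#' entropy of desorption via van't Hoff regression across `temps`, and (ii)
#' the analytic, temperature-dependent net isosteric heat surface via the
#' Clausius-Clapeyron relation. The two routes are intentionally kept side
#' by side: the regression value is a temperature-averaged enthalpy, while
#' the surface carries the explicit temperature dependence.
#'
#' @inheritParams predict_erh
#' @param emc_grid Strictly increasing moisture grid, kg/kg dry basis.
#' @param temps Temperatures in degC.
#' @return Object of class `thermo_curve`: list with tibbles `curve`
#'   (`emc`, `dH`, `dS`) and `surface` (`emc`, `temp_c`, `qst_j_mol`,
#'   `qst_kj_kg`), plus the generating `spec`. `tidy()` returns the curve;
#'   `tidy(x, "surface")` the surface.
#' @export
#' @examples
#' tc <- thermo_curves(reference_spec(), seq(0.05, 0.30, 0.05), seq(25, 65, 10))
#' tidy(tc)
thermo_curves <- function(spec, emc_grid, temps) {
  stopifnot(length(emc_grid) >= 1, length(temps) >= 1)
  if (is.unsorted(emc_grid, strictly = TRUE)) {
    stop("emc_grid must be strictly increasing", call. = FALSE)
  }
  curve <- if (length(unique(temps)) >= 2) {
    purrr::map_dfr(emc_grid, function(m) {
      tryCatch(vant_hoff_point(spec, m, temps),
               error = function(e) stop(sprintf(
                 "thermo_curves failed at emc = %.4g: %s", m,
                 conditionMessage(e)), call. = FALSE))
    })
  } else {
    tibble::tibble(emc = emc_grid, dH = NA_real_, dS = NA_real_)
  }
  surface <- tidyr::expand_grid(emc = emc_grid, temp_c = temps)
  surface$qst_j_mol <- net_isosteric_heat(spec, surface$emc, surface$temp_c)
  surface$qst_kj_kg <- j_mol_to_kj_kg(surface$qst_j_mol)
  structure(list(curve = curve, surface = surface, spec = spec,
                 temps = temps),
            class = "thermo_curve")
}

#' @export
print.thermo_curve <- function(x, ...) {
  cat("<thermo_curve>", x$spec$family,
      sprintf("| %d moisture levels x %d temperatures\n",
              nrow(x$curve), length(x$temps)))
  cat(sprintf("  dH range: %.3g - %.3g J/mol\n",
              min(x$curve$dH), max(x$curve$dH)))
  invisible(x)
}

#' @rdname thermo_curves
#' @param x A `thermo_curve`.
#' @param which `"curve"` (dH/dS vs moisture) or `"surface"` (qst over
#'   moisture and temperature).
#' @param ... Unused.
#' @export
tidy.thermo_curve <- function(x, which = c("curve", "surface"), ...) {
  which <- match.arg(which)
  x[[which]]
}
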