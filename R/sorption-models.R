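#' Physical constants used throughout the package
#'
#' Returns the universal gas constant, the molar mass of water and the
#' Celsius-to-Kelvin offset used consistently by every thermodynamic
#' computation in the package.
#'
#' @return A named list with elements `R` (8.314 J mol^-1 K^-1), `Ww`
#'   (0.018 kg mol^-1) and `celsius_offset` (273.15 K).
#' @export
#' @examples
#' thermo_constants()$R
thermo_constants <- function() {
  list(R = 8.314, Ww = 0.018, celsius_offset = 273.15)
}

.R_GAS <- 8.314
.WW <- 0.018
.K0 <- 273.15

#' Supported sorption model families
#'
#' The four three-parameter empirical desorption equations recommended by
#' the ASAE D245 standard for agricultural products.
#'
#' @return Character vector of the four family names.
#' @export
sorption_families <- function() {
  c("chung_pfost", "halsey", "henderson", "oswin")
}

match_family <- function(family) {
  match.arg(family, sorption_families())
}

#' Construct a sorption model specification
#'
#' Bundles a model family with its three parameters. The functional forms
#' (moisture content `M` in decimal dry basis, temperature `T` in degrees
#' Celsius) are:
#' \describe{
#'   \item{chung_pfost}{`ERH = exp(-(p1/(T + p3)) * exp(-p2 * M))`}
#'   \item{halsey}{`ERH = exp(-exp(p1 + p2*T) * (100*M)^(-p3))` --- note the
#'     moisture argument is percent dry basis (`100*M`), the convention
#'     under which published parameter sets for starchy products reproduce
#'     mid-range humidities}
#'   \item{henderson}{`ERH = 1 - exp(-p1 * (T + p2) * M^p3)`}
#'   \item{oswin}{`ERH = 1 / (1 + ((p1 + p2*T)/M)^p3)`}
#' }
#'
#' @param family One of [sorption_families()].
#' @param p1,p2,p3 Model parameters (units are family specific).
#' @return An object of class `sorption_spec`.
#' @export
#' @examples
#' sorption_spec("chung_pfost", 533.4351, 15.6235, 38.9053)
sorption_spec <- function(family, p1, p2, p3) {
  family <- match_family(family)
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(p3),
            length(p1) == 1, length(p2) == 1, length(p3) == 1,
            is.finite(p1), is.finite(p2), is.finite(p3))
  structure(list(family = family, p1 = p1, p2 = p2, p3 = p3),
            class = "sorption_spec")
}

#' @export
print.sorption_spec <- function(x, ...) {
  cat("<sorption_spec> family:", x$family,
      sprintf("| p1 = %.6g, p2 = %.6g, p3 = %.6g\n", x$p1, x$p2, x$p3))
  invisible(x)
}

#' @export
as.list.sorption_spec <- function(x, ...) unclass(x)

# Parameter-domain checks: errors, never silent NaN. Fitting relies on
# these to reject invalid steps explicitly.
check_spec_domain <- function(spec, temp_c) {
  f <- spec$family
  bad <- switch(f,
    chung_pfost = spec$p1 <= 0 || spec$p2 <= 0 || any(temp_c + spec$p3 <= 0),
    halsey = spec$p3 <= 0,
    henderson = spec$p1 <= 0 || spec$p3 <= 0 || any(temp_c + spec$p2 <= 0),
    oswin = spec$p3 <= 0 || any(spec$p1 + spec$p2 * temp_c <= 0)
  )
  if (bad) {
    stop(sprintf(
      "invalid %s parameters (p1=%.5g, p2=%.5g, p3=%.5g) at temperature %s degC",
      f, spec$p1, spec$p2, spec$p3, paste(unique(temp_c), collapse = ", ")),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Predicted equilibrium relative humidity
#'
#' Evaluates the sorption equation: the equilibrium relative humidity (water
#' activity, decimal) a material at moisture content `emc` attains at
#' temperature `temp_c`.
#'
#' @param spec A [sorption_spec()].
#' @param emc Equilibrium moisture content, kg water per kg dry matter
#'   (decimal dry basis). Vectorised.
#' @param temp_c Temperature in degrees Celsius. Vectorised (recycled
#'   against `emc`).
#' @return Numeric vector of ERH values, strictly in (0, 1).
#' @export
#' @examples
#' cp <- sorption_spec("chung_pfost", 533.4351, 15.6235, 38.9053)
#' predict_erh(cp, emc = 0.10, temp_c = 25)
predict_erh <- function(spec, emc, temp_c) {
  stopifnot(inherits(spec, "sorption_spec"))
  if (any(emc <= 0)) stop("emc must be > 0", call. = FALSE)
  check_spec_domain(spec, temp_c)
  p1 <- spec$p1; p2 <- spec$p2; p3 <- spec$p3
  out <- switch(spec$family,
    chung_pfost = exp(-(p1 / (temp_c + p3)) * exp(-p2 * emc)),
    halsey = exp(-exp(p1 + p2 * temp_c) * (100 * emc)^(-p3)),
    henderson = 1 - exp(-p1 * (temp_c + p2) * emc^p3),
    oswin = 1 / (1 + ((p1 + p2 * temp_c) / emc)^p3)
  )
  if (any(!is.finite(out))) {
    stop("sorption model evaluated to a non-finite value; check parameters",
         call. = FALSE)
  }
  out
}

#' Invert a sorption equation for moisture content
#'
#' Closed-form algebraic inverse of each sorption equation: the equilibrium
#' moisture content at a given relative humidity and temperature. Used by
#' the synthetic-data generator to place observations on a known isotherm
#' surface.
#'
#' @inheritParams predict_erh
#' @param erh Equilibrium relative humidity, decimal strictly in (0, 1).
#'   Vectorised.
#' @return Numeric vector of EMC values (kg/kg dry basis).
#' @export
#' @examples
#' cp <- sorption_spec("chung_pfost", 533.4351, 15.6235, 38.9053)
#' predict_emc(cp, erh = 0.174, temp_c = 25)
predict_emc <- function(spec, erh, temp_c) {
  stopifnot(inherits(spec, "sorption_spec"))
  if (any(erh <= 0 | erh >= 1)) stop("erh must be strictly in (0, 1)", call. = FALSE)
  check_spec_domain(spec, temp_c)
  p1 <- spec$p1; p2 <- spec$p2; p3 <- spec$p3
  out <- switch(spec$family,
    chung_pfost = -log(-log(erh) * (temp_c + p3) / p1) / p2,
    halsey = ((-log(erh)) / exp(p1 + p2 * temp_c))^(-1 / p3) / 100,
    henderson = (-log(1 - erh) / (p1 * (temp_c + p2)))^(1 / p3),
    oswin = (p1 + p2 * temp_c) / (1 / erh - 1)^(1 / p3)
  )
  if (any(!is.finite(out))) {
    stop("sorption model inversion produced a non-finite value", call. = FALSE)
  }
  out
}

#' Temperature derivative of log equilibrium relative humidity
#'
#' Analytic derivative d ln(ERH) / dT (per kelvin) at constant moisture
#' content, the quantity the Clausius-Clapeyron relation converts into the
#' net isosteric heat.
#'
#' @inheritParams predict_erh
#' @return Numeric vector, K^-1.
#' @export
dlnerh_dtemp <- function(spec, emc, temp_c) {
  stopifnot(inherits(spec, "sorption_spec"))
  if (any(emc <= 0)) stop("emc must be > 0", call. = FALSE)
  check_spec_domain(spec, temp_c)
  p1 <- spec$p1; p2 <- spec$p2; p3 <- spec$p3
  out <- switch(spec$family,
    chung_pfost = p1 * exp(-p2 * emc) / (temp_c + p3)^2,
    halsey = p2 * (-exp(p1 + p2 * temp_c) * (100 * emc)^(-p3)),
    henderson = {
      u <- p1 * (temp_c + p2) * emc^p3
      p1 * emc^p3 * exp(-u) / (1 - exp(-u))
    },
    oswin = {
      a <- p1 + p2 * temp_c
      r <- (a / emc)^p3
      -p3 * r / a * p2 / (1 + r)
    }
  )
  if (any(!is.finite(out))) {
    stop("derivative evaluated to a non-finite value; check parameters",
         call. = FALSE)
  }
  out
}

#' Net isosteric heat of desorption
#'
#' The excess over the latent heat of pure water required to desorb water
#' at constant moisture content, from the Clausius-Clapeyron relation:
#' `qst = R * Tabs^2 * d ln(ERH) / dT`, with `Tabs = temp_c + 273.15`.
#'
#' @inheritParams predict_erh
#' @return Net isosteric heat, J per mol of water. Vectorised.
#' @export
#' @examples
#' cp <- sorption_spec("chung_pfost", 533.4351, 15.6235, 38.9053)
#' net_isosteric_heat(cp, emc = 0.25, temp_c = 25) # ~1943 J/mol
net_isosteric_heat <- function(spec, emc, temp_c) {
  tabs <- temp_c + .K0
  .R_GAS * tabs^2 * dlnerh_dtemp(spec, emc, temp_c)
}

#' Convert a molar heat of water to a specific heat
#'
#' @param q_j_mol Heat in J per mol water.
#' @return Heat in kJ per kg water (divides by the molar mass of water,
#'   0.018 kg/mol, and by 1000).
#' @export
j_mol_to_kj_kg <- function(q_j_mol) q_j_mol / .WW / 1000

#' Reference fitted parameters for cassava products
#'
#' Pooled-fit parameter estimates (with standard errors) of the four
#' sorption equations for cassava flour and starch desorption isotherms
#' measured over 25--65 degC and 0.10--0.85 relative humidity. These serve
#' as the default "truth" for the synthetic-data generator and as reference
#' inputs for desk-scale thermodynamic calculations.
#'
#' @return A tibble with columns `family`, `p1`, `p2`, `p3`, `p1_se`,
#'   `p2_se`, `p3_se`, `see`, `mrpe`.
#' @export
#' @examples
#' cassava_reference_params()
cassava_reference_params <- function() {
  tibble::tribble(
    ~family,        ~see,   ~mrpe, ~p1,      ~p2,        ~p3,     ~p1_se,   ~p2_se,     ~p3_se,
    "chung_pfost",  0.0259, 5.96,  533.4351, 15.6235,    38.9053, 26.0750,  0.2109,     3.9891,
    "halsey",       0.0344, 10.71, 5.5667,   -0.0127,    2.0859,  0.1142998, 0.0008163, 0.0380959,
    "henderson",    0.0371, 9.52,  0.53096,  41.87321,   2.15928, 0.06678,  6.28502,    0.04235,
    "oswin",        0.0236, 5.12,  0.1783,   -0.0008338, 3.109,   0.00172,  0.00003531, 0.04018
  )
}

#' Reference sorption_spec for a family
#'
#' Convenience accessor returning [cassava_reference_params()] row as a
#' [sorption_spec()].
#'
#' @param family One of [sorption_families()].
#' @return A `sorption_spec`.
#' @export
reference_spec <- function(family = "chung_pfost") {
  family <- match_family(family)
  p <- cassava_reference_params()
  p <- p[p$family == family, ]
  sorption_spec(family, p$p1, p$p2, p$p3)
}
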