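#' Water evaporation rate of a drying batch
#'
#' `m_w = (W_ini / (1 + X_ini)) * (dX / dt)`: the dry-matter mass of the
#' batch times the rate of moisture loss on a dry basis.
#'
#' @param W_ini Initial (wet) batch weight, kg.
#' @param X_ini Initial moisture content, kg/kg dry basis.
#' @param dX Moisture-content reduction over the interval, kg/kg db
#'   (non-negative; re-wetting is not modelled).
#' @param dt Interval length, hours (> 0).
#' @return Evaporation rate, kg water per hour. Vectorised over `dX`/`dt`.
#' @export
#' @examples
#' evaporation_rate(100, 0.87, 0.10, 1) # 5.348 kg/h
evaporation_rate <- function(W_ini, X_ini, dX, dt) {
  if (W_ini <= 0) stop("W_ini must be > 0", call. = FALSE)
  if (X_ini < 0) stop("X_ini must be >= 0", call. = FALSE)
  if (any(dt <= 0)) stop("dt must be > 0", call. = FALSE)
  if (any(dX < 0)) stop("dX must be >= 0 (re-wetting is not modelled)", call. = FALSE)
  (W_ini / (1 + X_ini)) * (dX / dt)
}

#' Instantaneous energy efficiency of a dryer
#'
#' Ratio of the energy leaving as desorbed water vapour to the thermal
#' input rate. The dimensionally consistent form (default) is
#' `eta = m_w * (Qst / Ww) / Q_in`: the evaporation rate in kg/h divided by
#' the molar mass of water gives mol/h, times the isosteric heat in J/mol
#' gives J/h, converted to kJ/h and divided by the input rate. An
#' alternative "as-printed" form sometimes seen in the applied literature
#' multiplies by `Ww` instead; it is retained behind `as_printed = TRUE`
#' purely for auditability and is not dimensionally meaningful.
#'
#' @param m_w Water evaporation rate, kg/h.
#' @param Qst Total isosteric heat of desorption, J per mol water.
#' @param Q_in_rate Input energy rate of the dryer, kJ/h.
#' @param as_printed Use the non-consistent literature form (default FALSE).
#' @return Efficiency as a decimal. Values above 1 indicate an unphysical
#'   input combination and trigger a warning.
#' @export
#' @examples
#' drying_efficiency(5.348, 46100, 33000) # ~0.415
drying_efficiency <- function(m_w, Qst, Q_in_rate, as_printed = FALSE) {
  if (any(m_w <= 0) || any(Qst <= 0) || any(Q_in_rate <= 0)) {
    stop("m_w, Qst and Q_in_rate must all be > 0", call. = FALSE)
  }
  eta <- if (as_printed) {
    m_w * (Qst / 1000) * .WW / Q_in_rate
  } else {
    m_w * (Qst / 1000) / .WW / Q_in_rate
  }
  if (any(eta > 1 + 1e-9)) {
    warning("efficiency above 1: unphysical input combination")
  }
  eta
}

#' Construct a drying run
#'
#' A moisture-content time series together with the batch and dryer
#' constants needed for the energy-efficiency profile.
#'
#' @param time_h Sampling times, hours, strictly increasing.
#' @param x_db Moisture content at each time, kg/kg dry basis,
#'   non-increasing.
#' @param W_ini Initial batch weight, kg.
#' @param X_ini Initial moisture content, kg/kg db (default `x_db[1]`).
#' @param temp_c Drying-air temperature, degC.
#' @param Q_in_rate Input energy rate, kJ/h.
#' @return A tibble of class `drying_run` with columns `time_h`, `x_db` and
#'   the constants stored as attributes.
#' @export
drying_run <- function(time_h, x_db, W_ini, X_ini = x_db[1], temp_c,
                       Q_in_rate) {
  stopifnot(length(time_h) == length(x_db), length(time_h) >= 2)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing", call. = FALSE)
  }
  if (any(diff(x_db) > 0)) {
    stop("x_db must be non-increasing over time", call. = FALSE)
  }
  if (W_ini <= 0) stop("W_ini must be > 0", call. = FALSE)
  if (Q_in_rate <= 0) stop("Q_in_rate must be > 0", call. = FALSE)
  out <- tibble::tibble(time_h = time_h, x_db = x_db)
  attr(out, "W_ini") <- W_ini
  attr(out, "X_ini") <- X_ini
  attr(out, "temp_c") <- temp_c
  attr(out, "Q_in_rate") <- Q_in_rate
  class(out) <- c("drying_run", class(out))
  out
}

#' Per-interval energy-efficiency profile of a drying run
#'
#' For each interval of the moisture time series, computes the evaporation
#' rate, the total isosteric heat evaluated at the interval-mean moisture
#' content and the drying-air temperature, and the resulting instantaneous
#' efficiency. With a constant input rate the efficiency falls toward the
#' end of drying as the drying rate collapses and the isosteric heat rises.
#'
#' @param run A [drying_run()].
#' @param spec A fitted [sorption_spec()] supplying the isosteric heat.
#' @param as_printed Passed to [drying_efficiency()].
#' @return A tibble with one row per interval: `t_start`, `t_end`, `x_mean`,
#'   `m_w` (kg/h), `Qst` (J/mol) and `eta`.
#' @export
#' @examples
#' run <- simulate_drying_run(W_ini = 100, X_ini = 0.87, X_eq = 0.05,
#'                            k = 0.3, temp_c = 45, Q_in_rate = 33000,
#'                            n_points = 9)
#' efficiency_profile(run, reference_spec("chung_pfost"))
efficiency_profile <- function(run, spec, as_printed = FALSE) {
  stopifnot(inherits(run, "drying_run"), inherits(spec, "sorption_spec"))
  n <- nrow(run)
  i <- seq_len(n - 1)
  dt <- run$time_h[i + 1] - run$time_h[i]
  dX <- run$x_db[i] - run$x_db[i + 1]
  x_mean <- (run$x_db[i] + run$x_db[i + 1]) / 2
  m_w <- evaporation_rate(attr(run, "W_ini"), attr(run, "X_ini"), dX, dt)
  Qst <- total_isosteric_heat(spec, x_mean, attr(run, "temp_c"))
  eta <- rep(NA_real_, n - 1)
  pos <- m_w > 0
  if (any(pos)) {
    eta[pos] <- drying_efficiency(m_w[pos], Qst[pos], attr(run, "Q_in_rate"),
                                  as_printed = as_printed)
  } else {
    eta[!pos] <- 0
  }
  eta[!pos] <- 0
  tibble::tibble(
    t_start = run$time_h[i], t_end = run$time_h[i + 1],
    x_mean = x_mean, m_w = m_w, Qst = Qst, eta = eta
  )
}
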