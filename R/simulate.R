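#' Factorial desorption study design
#'
#' Describes the synthetic study the generator emulates: a full factorial
#' of 4 cassava products (flour and starch, unfermented and fermented) by
#' 5 temperatures (25--65 degC in 10 degC steps) by 6 relative-humidity
#' setpoints (0.85 down to 0.10 in decrements of 0.15), with 2 replicates.
#' The default truth is the modified Chung-Pfost reference parameter set;
#' additive product shifts are sized to contribute roughly 0.1 percent of
#' the total EMC variance, and Gaussian measurement noise on EMC defaults
#' to 0.008 kg/kg (the residual mean square typical of gravimetric
#' sorption systems, ~6.3e-5).
#'
#' @param products Product labels.
#' @param temps Temperatures, degC.
#' @param erh_levels Relative-humidity setpoints, decimals in (0, 1).
#' @param replicates Replicates per cell.
#' @param truth A [sorption_spec()] placing the true isotherm surface.
#' @param product_shift Additive EMC shift per product, kg/kg db (recycled
#'   or named by product).
#' @param noise_sd SD of additive Gaussian EMC noise, kg/kg db.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return A list of class `study_design`.
#' @export
study_design <- function(products = c("unfermented_flour", "fermented_flour",
                                      "unfermented_starch", "fermented_starch"),
                         temps = seq(25, 65, by = 10),
                         erh_levels = seq(0.85, 0.10, by = -0.15),
                         replicates = 2L,
                         truth = reference_spec("chung_pfost"),
                         product_shift = c(-1.5, -0.5, 0.5, 1.5) * 0.00198,
                         noise_sd = 0.008,
                         seed = 1L) {
  stopifnot(all(erh_levels > 0 & erh_levels < 1), noise_sd >= 0,
            replicates >= 1, inherits(truth, "sorption_spec"))
  shifts <- rep_len(product_shift, length(products))
  names(shifts) <- products
  structure(list(products = products, temps = temps,
                 erh_levels = erh_levels, replicates = as.integer(replicates),
                 truth = truth, product_shift = shifts,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a synthetic desorption dataset
#'
#' Places each design cell on the true isotherm surface by closed-form
#' inversion (`EMC = predict_emc(truth, erh, temp)`), adds the per-product
#' shift and Gaussian measurement noise on EMC (the physically measured
#' quantity in a gravimetric system), and truncates to positive values by
#' redrawing offending noise. Identical seeds yield identical datasets.
#'
#' @param design A [study_design()].
#' @return A tibble with columns `product`, `temp_c`, `erh`, `emc`,
#'   `replicate`.
#' @export
#' @examples
#' d <- simulate_isotherms(study_design(seed = 42))
#' range(d$emc)
simulate_isotherms <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  grid <- tidyr::expand_grid(
    product = design$products,
    temp_c = design$temps,
    erh = design$erh_levels,
    replicate = seq_len(design$replicates)
  )
  base <- tryCatch(
    predict_emc(design$truth, grid$erh, grid$temp_c),
    error = function(e) stop(sprintf(
      "design truth is invalid on the (erh, temp) grid: %s",
      conditionMessage(e)), call. = FALSE)
  )
  emc <- base + unname(design$product_shift[grid$product])
  withr::with_seed(design$seed, {
    if (design$noise_sd > 0) {
      noise <- stats::rnorm(nrow(grid), 0, design$noise_sd)
      out <- emc + noise
      while (any(out <= 0)) {
        bad <- out <= 0
        out[bad] <- emc[bad] + stats::rnorm(sum(bad), 0, design$noise_sd)
      }
      emc <- out
    }
  })
  grid$emc <- emc
  grid[, c("product", "temp_c", "erh", "emc", "replicate")]
}

#' Generate a synthetic drying run
#'
#' Exponential approach to an equilibrium moisture floor,
#' `X(t) = X_eq + (X_ini - X_eq) * exp(-k t)`, sampled on a regular time
#' grid, optionally with multiplicative measurement noise (monotonicity is
#' enforced by a running minimum so the run remains a valid drying curve).
#'
#' @param W_ini Initial batch weight, kg.
#' @param X_ini Initial moisture content, kg/kg db.
#' @param X_eq Equilibrium moisture floor, kg/kg db (must be below `X_ini`).
#' @param k First-order drying constant, 1/h (>= 0).
#' @param temp_c Drying-air temperature, degC.
#' @param Q_in_rate Input energy rate, kJ/h.
#' @param n_points Number of sampling times (including t = 0).
#' @param dt Sampling interval, hours.
#' @param noise_sd Relative noise SD on the moisture readings (default 0).
#' @param seed Seed used when `noise_sd > 0`.
#' @return A [drying_run()].
#' @export
simulate_drying_run <- function(W_ini, X_ini, X_eq, k, temp_c, Q_in_rate,
                                n_points = 13L, dt = 1, noise_sd = 0,
                                seed = 1L) {
  if (X_eq >= X_ini) stop("X_eq must be below X_ini", call. = FALSE)
  if (X_eq <= 0) stop("X_eq must be > 0", call. = FALSE)
  if (k < 0) stop("drying constant k must be >= 0", call. = FALSE)
  times <- (seq_len(n_points) - 1) * dt
  x <- X_eq + (X_ini - X_eq) * exp(-k * times)
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      x <- x * (1 + stats::rnorm(n_points, 0, noise_sd))
    })
    x <- pmax(cummin(x), X_eq * 0.5)
    x[1] <- X_ini
  }
  drying_run(times, x, W_ini = W_ini, X_ini = X_ini, temp_c = temp_c,
             Q_in_rate = Q_in_rate)
}
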