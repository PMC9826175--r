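#' Goodness-of-fit indices for sorption models
#'
#' Computes the three fit-quality indices conventional in sorption studies,
#' all on the relative-humidity scale: the coefficient of determination
#' R^2, the mean relative percentage error
#' `MRPE = (100/N) * sum(|obs - pred| / obs)`, and the standard error of
#' estimation `SEE = sqrt(sum((obs - pred)^2) / (N - n_params))`.
#'
#' @param observed,predicted Numeric vectors of equal length (ERH, decimal).
#' @param n_params Number of estimated model parameters (degrees of freedom
#'   are `N - n_params`).
#' @return A one-row tibble with columns `r2`, `mrpe`, `see`.
#' @export
#' @examples
#' goodness_of_fit(c(0.2, 0.4, 0.6, 0.8), c(0.22, 0.38, 0.63, 0.77), 3)
goodness_of_fit <- function(observed, predicted, n_params = 3L) {
  stopifnot(length(observed) == length(predicted),
            length(observed) > n_params)
  if (any(observed == 0)) {
    stop("MRPE is undefined when any observed value equals zero", call. = FALSE)
  }
  n <- length(observed)
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  tibble::tibble(
    r2 = 1 - rss / tss,
    mrpe = 100 / n * sum(abs(observed - predicted) / observed),
    see = sqrt(rss / (n - n_params))
  )
}

# Deterministic multi-start values per family: a field-typical centre for
# starchy products plus scaled perturbations, tried in fixed order.
fit_starts <- function(family) {
  centre <- switch(family,
    chung_pfost = c(p1 = 500, p2 = 15, p3 = 40),
    halsey = c(p1 = 5, p2 = -0.01, p3 = 2),
    henderson = c(p1 = 0.5, p2 = 40, p3 = 2),
    oswin = c(p1 = 0.15, p2 = -0.001, p3 = 3)
  )
  scales <- list(c(1, 1, 1), c(0.5, 1, 1), c(2, 1, 1),
                 c(1, 0.5, 0.5), c(1, 2, 2), c(0.5, 0.5, 1), c(2, 2, 1))
  lapply(scales, function(s) as.list(centre * s))
}

fit_formula <- function(family) {
  switch(family,
    chung_pfost = erh ~ exp(-(p1 / (temp_c + p3)) * exp(-p2 * emc)),
    halsey = erh ~ exp(-exp(p1 + p2 * temp_c) * (100 * emc)^(-p3)),
    henderson = erh ~ 1 - exp(-p1 * (temp_c + p2) * emc^p3),
    oswin = erh ~ 1 / (1 + ((p1 + p2 * temp_c) / emc)^p3)
  )
}

#' Fit a sorption equation to desorption data
#'
#' Nonlinear least squares on the relative-humidity scale: the residual for
#' each record is the observed (set-point) ERH minus the model ERH
#' evaluated at the measured moisture content and temperature. Estimation
#' uses the Gauss-Newton algorithm with step halving as implemented in
#' [stats::nls()], started from a deterministic sequence of
#' family-typical values; the converged fit with the lowest residual sum of
#' squares is returned.
#'
#' @param data A data frame with columns `erh` (decimal in (0,1)), `emc`
#'   (kg/kg dry basis) and `temp_c` (degC). Must span at least two distinct
#'   temperatures and three ERH levels.
#' @param family One of [sorption_families()].
#' @param start Optional named list `list(p1=, p2=, p3=)` used as the first
#'   (and preferred) start.
#' @param tol Convergence criterion passed to [stats::nls()] (relative
#'   offset), default `1e-6`.
#' @param max_iter Maximum Gauss-Newton iterations per start.
#' @return An object of class `sorption_fit`: a list with the fitted
#'   [sorption_spec()], per-parameter standard errors, residuals, fitted
#'   values, fit indices (`r2`, `mrpe`, `see`), iteration count and
#'   convergence flag. Supports [generics::tidy()], [generics::glance()]
#'   and [stats::predict()].
#' @export
#' @examples
#' d <- simulate_isotherms(study_design(noise_sd = 0, seed = 1))
#' fit <- fit_sorption(d, "chung_pfost")
#' glance(fit)
fit_sorption <- function(data, family, start = NULL, tol = 1e-6,
                         max_iter = 50L) {
  family <- match_family(family)
  data <- validate_isotherms(data, require_design = FALSE)
  if (length(unique(data$temp_c)) < 2) {
    stop("need at least 2 distinct temperatures to fit a sorption model",
         call. = FALSE)
  }
  if (length(unique(data$erh)) < 3) {
    stop("need at least 3 distinct ERH levels to fit a sorption model",
         call. = FALSE)
  }
  starts <- fit_starts(family)
  if (!is.null(start)) starts <- c(list(start[c("p1", "p2", "p3")]), starts)
  fml <- fit_formula(family)
  ctrl <- stats::nls.control(maxiter = max_iter, tol = tol, scaleOffset = 1,
                             minFactor = 1e-10)
  best <- NULL
  last_err <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::nls(fml, data = data, start = st, control = ctrl),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      last_err <- res
      next
    }
    if (is.null(best) || stats::deviance(res) < stats::deviance(best)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop(sprintf("fit_sorption(%s) failed to converge from any start: %s",
                 family, conditionMessage(last_err)), call. = FALSE)
  }
  cf <- stats::coef(best)
  spec <- sorption_spec(family, cf[["p1"]], cf[["p2"]], cf[["p3"]])
  pred <- stats::fitted(best)
  gof <- goodness_of_fit(data$erh, pred, n_params = 3L)
  structure(list(
    spec = spec,
    stderr = summary(best)$coefficients[, "Std. Error"],
    residuals = data$erh - pred,
    fitted = as.numeric(pred),
    r2 = gof$r2, mrpe = gof$mrpe, see = gof$see,
    n_iter = best$convInfo$finIter,
    converged = isTRUE(best$convInfo$isConv),
    n = nrow(data),
    data = data
  ), class = "sorption_fit")
}

#' @export
print.sorption_fit <- function(x, ...) {
  cat("<sorption_fit>", x$spec$family,
      sprintf("| n = %d, R2 = %.4f, MRPE = %.2f%%, SEE = %.4f\n",
              x$n, x$r2, x$mrpe, x$see))
  est <- unlist(x$spec[c("p1", "p2", "p3")])
  for (i in 1:3) {
    cat(sprintf("  p%d = %.6g +/- %.4g\n", i, est[i], x$stderr[i]))
  }
  invisible(x)
}

#' @rdname fit_sorption
#' @param x,object A `sorption_fit`.
#' @param ... Unused.
#' @export
tidy.sorption_fit <- function(x, ...) {
  est <- unlist(x$spec[c("p1", "p2", "p3")])
  tibble::tibble(
    term = c("p1", "p2", "p3"),
    estimate = unname(est),
    std.error = unname(x$stderr),
    statistic = unname(est / x$stderr),
    p.value = 2 * stats::pt(abs(unname(est / x$stderr)),
                            df = x$n - 3, lower.tail = FALSE)
  )
}

#' @rdname fit_sorption
#' @export
glance.sorption_fit <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    r.squared = x$r2, mrpe = x$mrpe, see = x$see,
    n_iter = x$n_iter, converged = x$converged, nobs = x$n
  )
}

#' @rdname fit_sorption
#' @param newdata Optional data frame with `emc` and `temp_c`.
#' @export
predict.sorption_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_erh(object$spec, newdata$emc, newdata$temp_c)
}

#' Shapiro-Wilk check of residual normality
#'
#' Reliability screen for a fitted sorption model: a model whose ERH
#' residuals are not plausibly normal is downgraded even if its fit indices
#' look acceptable.
#'
#' @param residuals Numeric vector, length >= 3 and not constant.
#' @param alpha Significance level for the normality flag (default 0.05).
#' @return One-row tibble with `statistic`, `p_value` and `normal` (logical,
#'   `p_value >= alpha`).
#' @export
residual_normality <- function(residuals, alpha = 0.05) {
  stopifnot(length(residuals) >= 3)
  if (stats::sd(residuals) == 0) {
    stop("residuals are constant; normality test is degenerate", call. = FALSE)
  }
  sw <- stats::shapiro.test(residuals)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value,
                 normal = sw$p.value >= alpha)
}

#' Fit and rank all four sorption equations
#'
#' Fits every family in [sorption_families()] to the same dataset and ranks
#' them by SEE, then MRPE. In agricultural engineering a fit is customarily
#' deemed good when MRPE is below 10 percent; the `good_fit` column applies
#' that threshold. A family whose fit fails is kept in the table with an
#' error message rather than aborting the comparison.
#'
#' @inheritParams fit_sorption
#' @param families Families to fit (default all four).
#' @return A tibble with one row per family (columns `family`, `r2`, `mrpe`,
#'   `see`, `p1`..`p3`, `good_fit`, `residuals_normal`, `error`), ranked
#'   best first, with the list of `sorption_fit` objects in attribute
#'   `"fits"`.
#' @export
compare_sorption_models <- function(data, families = sorption_families(),
                                    tol = 1e-6, max_iter = 50L) {
  fits <- purrr::map(families, function(f) {
    tryCatch(fit_sorption(data, f, tol = tol, max_iter = max_iter),
             error = function(e) e)
  })
  names(fits) <- families
  rows <- purrr::map2_dfr(fits, families, function(ft, f) {
    if (inherits(ft, "error")) {
      return(tibble::tibble(family = f, r2 = NA_real_, mrpe = NA_real_,
                            see = NA_real_, p1 = NA_real_, p2 = NA_real_,
                            p3 = NA_real_, good_fit = NA,
                            residuals_normal = NA,
                            error = conditionMessage(ft)))
    }
    tibble::tibble(
      family = f, r2 = ft$r2, mrpe = ft$mrpe, see = ft$see,
      p1 = ft$spec$p1, p2 = ft$spec$p2, p3 = ft$spec$p3,
      good_fit = ft$mrpe < 10,
      residuals_normal = residual_normality(ft$residuals)$normal,
      error = NA_character_
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(!is.na(.data$see)),
                         .data$see, .data$mrpe)
  attr(rows, "fits") <- fits
  rows
}
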