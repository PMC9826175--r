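#' Main-effects ANOVA of equilibrium moisture content
#'
#' Decomposes the variance of EMC into main effects of ERH level,
#' temperature level and product type, each treated as a categorical
#' factor, with eta-squared effect sizes (`SS_factor / SS_total`).
#' Interactions are excluded: in desorption studies of milled starchy
#' products they are routinely insignificant, and the factorial design
#' leaves them to the residual. Replicates are averaged per design cell
#' before the analysis, so a full `p x t x h` factorial yields
#' `p*t*h - 1 - (p-1) - (t-1) - (h-1)` residual degrees of freedom (107 for
#' a 4 x 5 x 6 design). With a balanced complete design the sequential
#' sums of squares equal the marginal ones, so term order is immaterial.
#'
#' @param data A data frame with columns `product`, `temp_c`, `erh`, `emc`
#'   (and optionally `replicate`).
#' @param average_replicates Average replicate EMC values per
#'   (product, temperature, ERH) cell before analysis (default `TRUE`).
#' @return A tibble with one row per factor plus a residual row: columns
#'   `factor`, `df`, `ss`, `ms`, `f`, `p`, `eta_sq`.
#' @export
#' @examples
#' d <- simulate_isotherms(study_design(seed = 1))
#' emc_anova(d)
emc_anova <- function(data, average_replicates = TRUE) {
  data <- validate_isotherms(data, require_design = TRUE)
  if (average_replicates) {
    data <- dplyr::summarise(
      dplyr::group_by(data, .data$product, .data$temp_c, .data$erh),
      emc = mean(.data$emc), .groups = "drop")
  }
  cells <- tidyr::expand_grid(product = unique(data$product),
                              temp_c = unique(data$temp_c),
                              erh = unique(data$erh))
  present <- dplyr::distinct(data, .data$product, .data$temp_c, .data$erh)
  if (nrow(present) < nrow(cells)) {
    stop("unbalanced design: the product x temperature x ERH factorial has empty cells",
         call. = FALSE)
  }
  data$erh_f <- factor(data$erh)
  data$temp_f <- factor(data$temp_c)
  data$prod_f <- factor(data$product)
  fit <- stats::aov(emc ~ erh_f + temp_f + prod_f, data = data)
  sm <- summary(fit)[[1]]
  tab <- tibble::tibble(
    factor = c("erh_level", "temperature_level", "product_type", "residual"),
    df = sm[["Df"]],
    ss = sm[["Sum Sq"]],
    ms = sm[["Mean Sq"]],
    f = sm[["F value"]],
    p = sm[["Pr(>F)"]]
  )
  ss_total <- sum(tab$ss)
  if (ss_total <= 1e-12 * max(1, mean(data$emc)^2) * nrow(data)) {
    warning("EMC is constant: all sums of squares are zero; F and eta_sq undefined")
    tab$eta_sq <- NA_real_
    return(tab)
  }
  tab$eta_sq <- ifelse(tab$factor == "residual", NA_real_, tab$ss / ss_total)
  tab
}
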