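#' Validate an isotherm dataset
#'
#' Checks column presence, numeric ranges and (optionally) the presence of
#' the design factors needed for ANOVA. Returned invisibly as a tibble so
#' user pipelines can keep chaining.
#'
#' @param data A data frame of equilibrium desorption records.
#' @param require_design Require the `product` column (and add
#'   `replicate = 1` when absent) so the factorial analysis can run.
#' @return The validated data as a tibble.
#' @export
validate_isotherms <- function(data, require_design = FALSE) {
  stopifnot(is.data.frame(data))
  needed <- c("temp_c", "erh", "emc")
  if (require_design) needed <- c("product", needed)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("isotherm data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  bad <- which(!is.finite(data$erh) | data$erh <= 0 | data$erh >= 1)
  if (length(bad)) {
    stop(sprintf("erh outside (0, 1) at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(data$emc) | data$emc <= 0)
  if (length(bad)) {
    stop(sprintf("emc must be positive; offending row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (require_design && !"replicate" %in% names(data)) data$replicate <- 1L
  data
}

#' Read an isotherm dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `product,temp_c,erh,emc,replicate` (`temp_c` in degC, `erh` decimal,
#' `emc` kg/kg dry basis). Malformed rows are reported with their line
#' numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of isotherm records.
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # readr's parse-issue warning is promoted to an error below
  data <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            product = readr::col_character(),
                            temp_c = readr::col_double(),
                            erh = readr::col_double(),
                            emc = readr::col_double(),
                            replicate = readr::col_integer()
                          )))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed CSV: parse failure at line %d (expected %s)",
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  validate_isotherms(data, require_design = TRUE)
}

#' Write an isotherm dataset to CSV
#'
#' @param data Isotherm records (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(data, path) {
  data <- validate_isotherms(data, require_design = TRUE)
  readr::write_csv(data, path)
  invisible(path)
}

#' Run the full desorption-thermodynamics pipeline
#'
#' Chains the analysis stages on one dataset: main-effects ANOVA of EMC,
#' fitting and ranking of the four sorption equations, thermodynamic curves
#' and the enthalpy-entropy compensation verdict for the best-fitting
#' family (and any additional requested families), and, when a drying run
#' is supplied, the dryer energy-efficiency profile. Stage failures are
#' caught and reported per stage; downstream stages that do not depend on
#' the failed one still run.
#'
#' @param data Isotherm records (see [validate_isotherms()]).
#' @param families Sorption families to fit.
#' @param emc_grid Moisture grid for thermodynamic curves and compensation.
#' @param temps Temperatures for the van't Hoff analysis; defaults to the
#'   distinct temperatures in `data`.
#' @param alpha Significance level used in reporting.
#' @param run Optional [drying_run()] for the efficiency stage.
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and the compensation verdict as JSON, each stamped with the seed and a
#'   hash of the configuration.
#' @param seed Seed recorded in the outputs (the pipeline itself is
#'   deterministic given `data`).
#' @return A list with elements `anova`, `model_comparison`, `fits`,
#'   `thermo`, `compensation`, `efficiency`, `errors`, plus the
#'   configuration stamp.
#' @export
#' @examples
#' d <- simulate_isotherms(study_design(seed = 7))
#' res <- run_sorption_pipeline(d)
#' res$compensation[["chung_pfost"]]
run_sorption_pipeline <- function(data,
                                  families = sorption_families(),
                                  emc_grid = seq(0.06, 0.28, by = 0.01),
                                  temps = NULL,
                                  alpha = 0.05,
                                  run = NULL,
                                  out_dir = NULL,
                                  seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  data <- validate_isotherms(data, require_design = TRUE)
  if (is.null(temps)) temps <- sort(unique(data$temp_c))
  errors <- list()
  capture <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }

  anova_tab <- capture("anova", emc_anova(data))
  comparison <- capture("fit", compare_sorption_models(data))
  fits <- if (!is.null(comparison)) attr(comparison, "fits") else list()

  thermo <- list()
  compensation <- list()
  for (f in families) {
    ft <- fits[[f]]
    if (is.null(ft) || inherits(ft, "error")) next
    thermo[[f]] <- capture(paste0("thermo_", f),
                           thermo_curves(ft$spec, emc_grid, temps))
    compensation[[f]] <- capture(paste0("compensation_", f),
                                 compensation_analysis(ft$spec, emc_grid,
                                                       temps,
                                                       conf_level = 1 - alpha))
  }

  efficiency <- NULL
  if (!is.null(run)) {
    best <- if (!is.null(comparison)) comparison$family[1] else families[1]
    if (!is.null(fits[[best]]) && !inherits(fits[[best]], "error")) {
      efficiency <- capture("efficiency",
                            efficiency_profile(run, fits[[best]]$spec))
    }
  }

  stamp <- list(seed = seed,
                config_hash = rlang::hash(list(families, emc_grid, temps,
                                               alpha, seed)))
  out <- list(anova = anova_tab, model_comparison = comparison, fits = fits,
              thermo = thermo, compensation = compensation,
              efficiency = efficiency, errors = errors, stamp = stamp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(anova_tab)) {
      readr::write_csv(anova_tab, file.path(out_dir, "anova.csv"))
    }
    if (!is.null(comparison)) {
      readr::write_csv(dplyr::select(comparison, -dplyr::any_of("fits")),
                       file.path(out_dir, "model_comparison.csv"))
    }
    for (f in names(thermo)) {
      if (is.null(thermo[[f]])) next
      readr::write_csv(tidy(thermo[[f]], "surface"),
                       file.path(out_dir, paste0("qst_surface_", f, ".csv")))
      readr::write_csv(tidy(thermo[[f]], "curve"),
                       file.path(out_dir, paste0("enthalpy_entropy_", f, ".csv")))
    }
    comp_json <- purrr::map(purrr::compact(compensation),
                            ~ as.list(tidy(.x)))
    jsonlite::write_json(c(comp_json, stamp),
                         file.path(out_dir, "compensation.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(efficiency)) {
      readr::write_csv(efficiency, file.path(out_dir, "efficiency_profile.csv"))
    }
  }
  out
}
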