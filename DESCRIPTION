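Package: sorptherm
Title: Sorption Thermodynamics of Dried Food Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the four modified ASAE sorption equations (Chung-Pfost,
    Halsey, Henderson, Oswin) to equilibrium desorption data, derives the
    net and total isosteric heat of desorption analytically from the
    Clausius-Clapeyron relation, tests enthalpy-entropy compensation with
    the Krug procedure (isokinetic versus harmonic-mean temperature), runs
    main-effects ANOVA of equilibrium moisture content on humidity,
    temperature and product type, and evaluates the instantaneous energy
    efficiency of batch dryers from moisture-content time series. Includes
    a synthetic-data generator that emulates a full factorial desorption
    study for starchy products such as cassava flour and starch.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
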