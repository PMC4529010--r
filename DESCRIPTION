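Package: stoveuse
Title: Performance-Usage Modelling of Cookstove Interventions for Household Air Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative guidance for cookstove performance and usage:
    a minute-resolution single-zone (box) model of kitchen PM2.5 and CO
    concentrations under piecewise-constant emission schedules, an IWA
    11:2012 performance-tier registry with classification, a
    stove-displacement scenario engine with source apportionment and
    inversion for usage-time and displacement thresholds against WHO
    guideline targets, an integrated exposure-response mapping from
    kitchen concentration to child ALRI relative risk, and
    thermal-efficiency-based fuel-savings calculations. All results are
    tidy tibbles; ggplot2 autoplot methods are provided for the main
    result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
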