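Package: mubudget
Title: Measurement Uncertainty Budgets by GUM Propagation and Monte Carlo
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up evaluation of measurement uncertainty for analytical
    assays with product-form content models, following the Guide to the
    Expression of Uncertainty in Measurement (GUM) and its Supplement 1.
    Builds uncertainty budgets from Type A statistics (repeatability,
    system-suitability series, calibration-curve prediction) and Type B
    distribution conversions (rectangular, triangular), combines relative
    standard uncertainties through the law of propagation, propagates full
    probability distributions by Monte Carlo simulation, and validates the
    GUM coverage interval against the Monte Carlo interval with the
    Supplement 1 numerical tolerance. Ships a worked uncertainty budget for
    an HPLC-UV assay of the antiemetic Metopimazine as a packaged fixture,
    plus a synthetic raw-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
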