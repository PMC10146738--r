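Package: relkin
Title: Release Kinetics of Drug-Loaded Fabrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies drug loading and cumulative release of drug-loaded
    viscose fabrics from UV-vis absorbance readings, fits the four classical
    release-kinetics models (zero-order, first-order, Higuchi,
    Korsmeyer-Peppas) by least squares with the Korsmeyer-Peppas 60 percent
    validity restriction, compares models on adjusted R-squared, residual
    sum of squares, reduced chi-squared and Pearson's r, classifies the
    release mechanism from the power-law exponent with cylinder thresholds,
    flags burst release, and computes Hoftyzer-Van Krevelen
    group-contribution solubility parameters. Includes a synthetic
    release-curve generator and a registry of reference fitted equations so
    every stage of the pipeline is testable without raw experimental data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
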