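Package: adipocut
Title: Anthropometric Obesity Indices and Probability-Based Cut-Point
    Derivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sex-stratified prediction of DXA whole-body fat percentage and
    visceral adipose tissue (VAT) mass from five anthropometric indices
    (BMI, waist circumference, waist-to-hip ratio, waist-to-height ratio and
    waist/sqrt(height)), with AIC-based comparison of the candidate
    predictors and derivation of index cut-points that give a chosen
    probability (default 0.75) that an individual exceeds an obesity
    threshold, given the regression prediction error. Includes a calibrated
    synthetic-cohort generator emulating the per-sex structure of a DXA
    validity study, geometric-mean summaries for log-normal outcomes, and
    tidy/ggplot2 methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
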