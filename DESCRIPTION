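Package: dkdrules
Title: Stratified Association-Rule Analysis of Kidney Outcomes in Diabetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining single-antecedent association rules between
    routine health-examination risk factors and five-year kidney outcomes in
    diabetic cohorts. Provides a synthetic longitudinal cohort generator with
    configurable factor-to-outcome effects, eligibility and baseline selection
    for annual-examination data, eGFR computation with the Japanese
    serum-creatinine equation, a >= 30 percent eGFR-decline outcome
    definition, sex-specific percentile binarization of risk factors,
    modified KDIGO risk-category staging with dipstick proteinuria, and
    per-stratum confidence and lift tables with bubble-grid plots.
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
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
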