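Package: mfindex
Title: Multimorbidity Frailty Index from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a cumulative-deficit multimorbidity frailty index (mFI)
    from administrative health-insurance claims. Starting from beneficiary
    registry and outpatient/inpatient claim tables with ICD-9-CM diagnosis
    codes, the package screens a study cohort of older adults, selects
    deficit items by prevalence and age-trend criteria on 3-digit code
    roots, scores each person as the fraction of deficits present,
    assigns frailty categories, derives mortality, unplanned-hospitalization
    and intensive-care outcomes, and quantifies the index's predictive
    association via Kaplan-Meier curves, log-rank tests, Cox proportional
    hazards models and logistic discrimination statistics. A synthetic
    claims generator with known ground truth supports end-to-end testing.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
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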