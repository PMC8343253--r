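Package: growthdyn
Title: Growth Dynamics and LMS Reference Analytics for Pediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing linear growth of children across weight
    strata in mixed cross-sectional/longitudinal cohorts: LMS (Box-Cox)
    standard-deviation-score referencing and centile tables, penalized
    maximum-likelihood fitting of L/M/S curves for building
    population-specific height references, growth-velocity computation with
    plausibility filters, per-age-group two-group contrasts with Holm-Sidak
    correction, cross-lagged BMI-to-height effect estimation,
    random-intercept piecewise trend models, endocrine panel contrasts
    (including HOMA-IR), and a seeded synthetic cohort generator that plants
    configurable obesity effects on height, growth velocity, and hormone
    profiles for end-to-end validation.
License: MIT
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
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
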