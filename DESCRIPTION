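Package: oncoclaims
Title: Incident Cancer Case Ascertainment in Administrative Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies incident breast, prostate and colorectal cancer cases
    in longitudinal statutory-health-insurance claims data using a family of
    parameterised case-finding algorithms (lookback/washout screening,
    confirmation-window logic, configurable confirmatory events), and
    estimates crude and age-standardised cumulative incidences with direct
    standardisation to the 1976 European Standard Population. Ships a
    synthetic claims simulator with ground-truth cancer histories so that
    algorithm sensitivity and positive predictive value, which cannot be
    measured on real unlinked claims, can be studied end to end, together
    with registry-style benchmarking and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lubridate,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
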