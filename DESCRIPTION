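Package: recruitqc
Title: Quality Control and Gaming Detection for Online Recruitment Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens, geographically validates, and de-duplicates online
    recruitment questionnaire submissions. Implements an eligibility screen,
    reconciliation of self-reported postal codes with IP-derived region,
    clustering of submissions linked by shared IP addresses or same/variant
    email addresses ("gaming" detection), paradata comparisons (missingness,
    completion time, proportion tests, stepwise logistic regression),
    per-mode recruitment efficiency accounting, and staged participant-flow
    reporting with conservation checks. Includes a synthetic-cohort simulator
    with ground-truth labels and a deterministic benchmark cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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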