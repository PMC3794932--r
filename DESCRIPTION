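Package: pace
Title: Prescription Patterns Around Clinical Events from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how prescribers react to clinical events recorded in
    electronic health records. Detects events such as threshold-crossing
    laboratory values or nominal test outcomes, anchors a six-day observation
    window around each event, pools prescription counts across eligible
    windows, and computes the prescription change index (PCI): the ratio of
    the average slope of the cumulative prescription count after the event to
    the slope before it. Each drug is classified into an intervention,
    maintenance, or discontinuation pattern. Also provides an exact binomial
    test alternative, per-prescriber patterns with Cohen's kappa agreement
    against stated knowledge, PCI profiles across event severity or clinical
    condition, and a seeded synthetic inpatient-cohort generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
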