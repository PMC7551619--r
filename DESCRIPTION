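Package: threshpanel
Title: Detection and Rejection Threshold Analysis for Forced-Choice Sensory Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing forced-choice ascending-series sensory panel
    data. Implements per-panelist best estimate thresholds (BETs) under a
    modified ASTM E679 decision rule with an adaptation branch and
    non-responder imputation, group geometric-mean summaries and comparisons
    on logged BETs, the graphical group-threshold method (0/1 regression on
    log concentration inverted at a chance-adjusted criterion with inverse
    prediction confidence bounds), consistency-gated consumer rejection
    thresholds from paired preference data, and a seeded synthetic-panel
    generator (log-normal individual thresholds, a specific-anosmia
    subpopulation, adaptation carryover, preference segmentation) for
    testing every stage without raw response data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
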