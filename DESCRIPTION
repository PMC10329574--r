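Package: polypval
Title: Sensitivity Analysis of Validation Metrics for Polyp Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation toolkit for object-level validation of polyp
    detection algorithms on multi-center colonoscopy frame datasets.
    Implements configurable localization criteria (box, mask and convex-hull
    intersection over union, point-in-region, center distance), greedy
    one-to-one assignment, object-level counting metrics (sensitivity,
    positive predictive value, F-beta) and 101-point interpolated average
    precision with threshold sweeps and threshold-range means. Provides
    stratified multi-center reporting (per-center metric panels,
    size-stratified average precision with across-center spread), comparison
    tables across localization criteria, and agreement analysis against
    binary clinician usefulness ratings. Ships a seeded synthetic-data
    generator that emulates multi-center single-frame polyp datasets
    (per-center prevalence, polyp size mixtures, convex and non-convex
    reference shapes) together with detector-like box predictions with
    size-dependent miss rates, localization jitter and confidence noise, so
    every analysis stage is testable without access to clinical data.
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
    optparse,
    png,
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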