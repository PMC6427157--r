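Package: cnemss
Title: Scoring, Reliability and Validity Analysis for the Chinese Nutrition
    Environment Measures Survey for Stores (C-NEMS-S)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Chinese adaptation of the Nutrition Environment
    Measures Survey for Stores (C-NEMS-S) as a reusable audit pipeline: the
    full 12-measure scoring sheet (availability, price and quality points),
    brute-force derivation of attainable score ranges, inter-rater
    reliability statistics (two-way random-effects absolute-agreement ICC and
    Cohen's kappa with interpretation bands), known-groups construct-validity
    comparisons (store-type contrasts via pooled t and exact Fisher tests,
    healthier-versus-regular price contrasts via the paired signed-rank
    test), and a seeded synthetic-audit generator calibrated to the study's
    store-type availability and price structure so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
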