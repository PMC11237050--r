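Package: findiv
Title: Finger Individuation Analysis for Multi-Channel Isometric Force Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies finger individuation from 10-channel isometric
    fingertip-force recordings of single-finger press trials. Estimates
    within-hand force overflow ("enslaving") and across-hand overflow
    ("mirroring") as origin-constrained robust-regression log-slopes over
    all instructed/uninstructed finger pairs, assesses split-half pattern
    reliability with Fisher-Z pooling, tests between-group pattern
    similarity with a leave-one-out cross-validated correlation, and runs
    symptomatic-finger clinical contrasts (pair-category ANOVA, paired
    tests). Includes a synthetic-cohort generator with known ground-truth
    coupling so every pipeline stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
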