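Package: facebias
Title: Signal Detection Analysis of Algorithm-Induced Bias in Face Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how prior face-recognition-algorithm decisions
    bias human similarity-confidence judgments in unfamiliar face matching,
    with and without face masks. Implements equal-variance Gaussian signal
    detection summaries (sensitivity d', criterion c, percent correct) from
    7-point rating data, the criterion-shift cognitive-bias statistic
    (delta c), rating-scale ROC curves with trapezoidal AUC, constant-criterion
    (isobias) curves and bands with overlap detection, bootstrap resampling
    over reviewers for confidence intervals and shift tests, mixed and one-way
    ANOVAs on panel accuracy and confidence, and a seeded synthetic
    reviewer-panel generator so every stage of the pipeline is testable
    without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
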