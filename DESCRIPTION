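Package: pbsvr
Title: Plackett-Burman Screening with a Support-Vector Surrogate for
    Cell-Culture Medium Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-level Plackett-Burman screening of culture-medium
    supplements and for cross-checking the screen with a machine-learning
    surrogate. Implements design generation and validation, coded/natural
    unit conversion, range analysis and single-degree-of-freedom contrast
    ANOVA for orthogonal two-level designs, an epsilon-support-vector
    regression trained by a sequential-minimal-optimization solver with a
    radial-basis kernel, genetic-algorithm hyperparameter tuning,
    mean-impact-value perturbation importance, response exploration over
    factor-level corners and grids, and a synthetic-data generator with
    power/type-I-error recovery reports. Ships the 12-run, 7-supplement
    CHO-cell serum-free-medium screen used throughout the documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
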