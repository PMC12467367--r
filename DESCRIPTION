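Package: raschkey
Title: Rasch Measurement, Key Forms and Change Detection for Clinical
    Ordinal Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates dichotomous, rating-scale, partial-credit and
    grouped-threshold Rasch models for clinical ordinal instruments by joint
    maximum likelihood, screens scales with standard psychometric criteria
    (rating-category diagnostics, infit/outfit mean squares and standardized
    fit, point-measure correlations, principal components analysis of
    residuals, separation and reliability), converts raw scores to logit
    measures with model standard errors via conversion tables, lays out key
    forms and imputes up to four missing ratings from them, and tests
    pre-post change for statistical significance with the sum-of-standard-
    errors rule. Includes a synthetic-response generator emulating a 49-item
    mixed-category neurobehavioral stroke subscale and a 20-item activities-
    of-daily-living scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
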