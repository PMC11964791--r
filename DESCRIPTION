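Package: codameta
Title: Compositional Meta-Analysis of 24-Hour Movement Behaviors and Adiposity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analyzing associations between 24-hour movement
    behavior compositions (sleep, sedentary time, light and moderate-to-vigorous
    physical activity) and adiposity outcomes in children and adolescents.
    Implements pivot (isometric log-ratio) coordinates for 4-part time-use
    compositions, all-for-one minute reallocations, per-study re-estimation of
    first-pivot-coordinate regression coefficients from individual-level data,
    conversion of extracted coefficients into absolute outcome-change effect
    sizes with variances (including standard-error reconstruction from
    confidence intervals or p-values and a delta-method transformation for
    log-scale outcomes), generic inverse-variance random-effects pooling with
    REML heterogeneity estimation, restricted-cubic-spline meta-regression on
    study mean age, and a truth-known synthetic corpus generator for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
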