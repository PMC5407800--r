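Package: cutselect
Title: Optimal Number and Location of Cutoff Points for Continuous Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Categorizes a continuous risk factor (biomarker) into ordinal risk
    groups by choosing both the optimal number of cutoff points, via AIC
    minimization over candidate group counts, and their optimal locations, via
    exhaustive significance-maximizing search (log-rank or likelihood-ratio
    tests under Cox proportional hazards for survival outcomes;
    likelihood-ratio or maximum-AUC criteria under logistic regression for
    binary outcomes). Includes a Pearson chi-square baseline search, hold-out
    validation with adjustment covariates, a spline-based smoothed
    hazard-ratio curve as a graphical aid, seeded synthetic-cohort generators
    with known true cutpoints, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    splines,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
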