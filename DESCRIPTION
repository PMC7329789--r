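Package: underreport
Title: Reporting Completeness of Sensitive Events in Complex Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify under-reporting of sensitive pregnancy
    outcomes (notably induced abortion) in stratified, clustered, weighted
    fertility surveys. Weighted survey event counts with design-based
    standard errors are compared to external benchmark counts built by
    linear interpolation and apportionment of sparse anchor data, yielding
    percent-reported estimates with 95% confidence intervals and a
    conservative non-overlap significance rule. A Monte Carlo module
    quantifies the bias that differential under-reporting (perfect
    specificity, imperfect sensitivity) induces in logistic-regression
    coefficients, with an exact analytic large-sample oracle. A synthetic
    cohort generator with known truth makes every estimator testable by
    parameter recovery without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
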