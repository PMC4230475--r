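Package: coxsens
Title: Omitted-Covariate Bias and Sensitivity Analysis for the Cox Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the asymptotic bias of treatment-effect estimates from
    Cox proportional hazards models when a relevant covariate is omitted, and
    corrects point estimates, P-values and confidence intervals given assumed
    sensitivity parameters (the omitted covariate's log-hazard effect and its
    conditional distribution given exposure). Implements the large-sample
    partial-likelihood score limit and its special cases (binary treatment,
    no censoring, first-order Taylor and rare-event approximations), an
    empirical score map built from Breslow-type baseline and reverse-role
    censoring survivor estimators, parametric-bootstrap highest-density
    confidence intervals, and a synthetic-data simulation engine for bias
    curves, censoring calibration and coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
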