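Package: survtransport
Title: Transporting Trial Survival Effects to Target Populations with
    Subgroup Discovery and Absolute-Benefit Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transposing a randomized trial's hazard ratio for a
    time-to-event outcome to a real-world target population using inverse
    odds of sampling weights (logistic-regression or discrete Bayesian
    network membership models, weighted Cox regression with robust variance,
    Kish effective sample size), for data-driven discovery and held-out
    validation of patient subgroups with heterogeneous treatment benefit
    (elastic-net treatment-interaction screening followed by a shallow
    benefit-contrast tree), for absolute-scale clinical benefit at a landmark
    time (G-computation risks, absolute risk reduction with bootstrap
    confidence intervals, number needed to treat, Gail-Simon qualitative and
    quantitative interaction tests), and for propensity-score matched
    external-validation emulation (nearest-neighbor matching on the logit
    distance, standardized-mean-difference balance assessment). A synthetic
    cohort generator with a Gaussian-copula covariate model and Weibull
    proportional-hazards outcomes supports fully reproducible end-to-end
    runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
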