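Package: aaagrowth
Title: Stochastic Growth Modelling of Abdominal Aortic Aneurysm Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the growth of abdominal aortic
    aneurysms (AAA) from longitudinal CT measurements of maximum diameter
    and volume. Implements a hierarchical stochastic growth model in which
    each subject's size follows geometric Brownian motion with a
    subject-specific average exponential rate drawn from a lognormal
    population distribution, with optional multiplicative measurement
    error; marginal maximum-likelihood fitting via Gauss-Hermite
    quadrature; population growth-distribution quantiles and means;
    per-subject rate estimation; a random-slope cube-law model relating
    volume to maximum diameter; repeated-measures correlation;
    leave-one-out predictive-quantile calibration; and a synthetic-cohort
    simulator for testing every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
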