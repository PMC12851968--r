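Package: cardiosig
Title: Cardiac Autonomic Signatures from Exercise R-R Interval Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling beat-to-beat R-R interval (RRi) recordings
    acquired across a rest-exercise-recovery protocol. Provides a synthetic
    RRi and immune-cohort generator, preprocessing (zero-phase Butterworth
    low-pass filtering and local-regression/MAD ectopic-beat rejection),
    robust estimation of the seven-parameter coupled-logistic cardiac
    autonomic signature (CAS) by box-constrained quasi-Newton optimisation
    with a Huber loss, and a second-stage Bayesian multivariate regression
    of CAS parameters on standardized immune-cell predictors with SEXIT
    posterior summaries (median, 95% HDI, probability of direction, ROPE
    exceedance) and MCMC convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
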