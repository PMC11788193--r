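Package: rnstates
Title: Latent Seizure Risk States and State-Dependent Neurostimulation
    Effects from Hourly Device Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers latent low/high seizure-risk states from hourly
    responsive-neurostimulation telemetry (interictal epileptiform activity
    and long-episode counts) and quantifies state-dependent associations
    between stimulation parameters and hourly risk-state transitions.
    Provides a seeded synthetic-cohort generator with known ground truth,
    preprocessing of burst-level stimulation records (burst averaging,
    start-of-hour imputation, zeroing rules, epoch filters), circadian and
    multidien cycle-phase features via zero-phase Butterworth filtering and
    the Hilbert transform, a multivariate Gaussian hidden Markov model fit
    by EM with AIC-based state-count selection, and per-stratum mixed-effects
    logistic transition models with Holm-adjusted inference and
    marginal/conditional R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
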