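Package: reassureHMM
Title: Hidden Markov Models for Clinician Reassurance Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bernoulli-emission hidden Markov models to collections of
    short, independent binary time series of clinician reassurances
    (cognitive vs. affective), pooled over sessions. Supports homogeneous
    baseline chains with stationary initial distributions,
    covariate-dependent transition probabilities through an inverse-logit
    link (lagged patient response and log duration of the previous
    reassurance), clinician fixed effects, joint maximum-likelihood
    estimation with multiple restarts, inverse-Hessian Wald confidence
    intervals, AIC model comparison, Viterbi global decoding, covariate
    profile curves, and a synthetic session generator emulating the
    structure of review-consultation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
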