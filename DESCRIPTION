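Package: ddmlearn
Title: Continuous-Time Drift Diffusion Models of Perceptual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits drift diffusion models (DDM) whose drift rate and response
    boundary evolve over training according to exponential learning
    trajectories, to trial-level response-time and choice data from
    multi-day perceptual learning experiments.  Provides the exact
    two-boundary Wiener first-passage-time likelihood, four candidate
    learning dynamics (constant, continuous, day-resetting, flexible) and
    the six model combinations built from them, per-participant maximum
    likelihood and adaptive-MCMC Bayesian backends, model comparison by
    Pareto-smoothed importance-sampling leave-one-out cross-validation
    (PSIS-LOO) and bridge-sampling Bayes factors, an accuracy-only logistic
    psychometric baseline with time-varying thresholds, absolute-fit
    assessment on trial blocks, and a synthetic-data generator reproducing
    the randomized-coherence dot-motion design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
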