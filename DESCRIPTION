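Package: motorhgf
Title: Hierarchical Gaussian Filter Analysis of Reward-Based Motor
    Sequence Learning
Version: 0.1.0
Authors@R:
    person("Open", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse reward-based motor sequence learning
    experiments in which trial-wise feedback scores reward a target
    pattern of inter-keystroke interval differences. Implements the
    reward mapping of the task, a two-level Hierarchical Gaussian
    Filter for continuous inputs with a family of eight linear
    response models, random-effects Bayesian model selection over
    models and model families, beta-band oscillation-burst detection
    with life-time exponent estimation, Welch and Morlet spectral
    power analysis, trial-wise regression of feedback-locked beta
    activity on precision-weighted prediction errors, and the
    nonparametric group statistics (permutation tests, adaptive FDR,
    probability-of-superiority effect sizes, bootstrap confidence
    intervals) used throughout. A synthetic-data module generates
    every input the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
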