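Package: sceptic
Title: Temporal Basis Function Reinforcement Learning for the Clock Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the 4-second "clock" reinforcement
    learning task. Implements the SCEPTIC family of temporal basis function
    models (selective maintenance, full maintenance, and a Kalman-filter
    uncertainty-tracking variant), hierarchical maximum a posteriori fitting
    with population shrinkage, extraction of trial-level decision signals
    (reward prediction error, entropy of the value distribution, the global
    value maximum and its location, uncertainty percentile), construction of
    duration-modulated convolved regressors for model-based fMRI, behavioral
    indices of exploration and exploitation with mixed-effects designs,
    counting-process survival tables with time-varying value and uncertainty
    covariates, and hippocampal long-axis geometry utilities (rotation,
    quantile binning, event-locked time courses). A synthetic-data module
    generates complete study-scale datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    lme4,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
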