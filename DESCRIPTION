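Package: credassign
Title: Credit Assignment in Reinforcement Learning with Neural State
    Representation Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a family of Rescorla-Wagner reinforcement learning models
    with credit-assignment (credit-spreading) parameters to trial-level
    investment behavior from iterated trust-game and matched bandit tasks,
    and relates credit assignment precision to the fidelity of multivoxel
    state representations.  Includes maximum-likelihood model fitting and
    AIC model comparison, model confusability and parameter-recovery
    validation, time-lagged behavioral regressions, representational
    similarity analysis (RDM regression, spherical searchlight,
    valence-split and cross-timepoint RSA), group-level sign-flip cluster
    permutation inference, and seeded synthetic generators for behavior and
    voxel patterns so that every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
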