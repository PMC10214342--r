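Package: cortherit
Title: Repeatability and Heritability of Circadian Cortisol Reaction Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for partitioning variance in longitudinal urinary
    cortisol measurements from wild primate communities. Builds the additive
    genetic relationship matrix from a pedigree, prepares raw sample tables
    (specific-gravity correction, reproductive-state assignment, exclusion
    rules, circadian and circannual covariate encoding), fits Bayesian
    hierarchical reaction-norm and animal models with genetic, maternal,
    individual and community random effects via JAGS, derives repeatability
    and heritability estimates with credible intervals, compares models by
    Pareto-smoothed importance-sampling leave-one-out cross-validation, and
    tests maternal versus genetic variance contributions against a
    within-community identity-permutation null. Includes a full generative
    simulator with known variance components for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
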