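Package: boutgrow
Title: Feeding-Bout Dynamics and Insect Growth to Maturity
Version: 0.1.0
Authors@R: person("boutgrow", "developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Likelihood-based analysis of alternating feeding/nonfeeding bout
    records from larval feeding trials under a two-state (telegraph)
    behavioural model: exact occupation-time densities, maximum-likelihood
    estimation of switch rates with percentile-bootstrap confidence
    intervals, estimation of mass gain per hour of feeding, and stochastic
    simulation of the joint distribution of age and mass at maturity under a
    critical-weight and juvenile-hormone-degradation model of larval
    development. Includes a synthetic-data generator mirroring the trial
    design and a subcommand-style command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
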