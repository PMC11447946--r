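Package: tacropop
Title: Population Pharmacokinetics of Once-Daily Extended-Release Tacrolimus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling of the
    once-daily extended-release formulation of tacrolimus in de novo kidney
    transplant recipients. Implements the closed-form two-compartment oral model
    with absorption lag time, hematocrit standardization of whole-blood
    concentrations to 45%, a CYP3A5/age/allometric covariate model, Laplacian
    (FOCE-type) marginal-likelihood estimation with empirical-Bayes estimates
    and shrinkage, stepwise covariate selection, non-compartmental exposure
    metrics (linear-up/log-down AUC over the dosing interval, trough
    extraction, geometric means), prediction-corrected visual predictive
    checks, a nonparametric bootstrap, a Monte-Carlo dose-scenario simulator
    stratified by genotype, age and hematocrit, and a synthetic study-design
    generator emulating a de novo transplant trough-plus-rich sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
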