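Package: neovanc
Title: Population Pharmacokinetics of Vancomycin in NICU Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population-pharmacokinetic modelling of
    intravenous vancomycin in neonatal intensive-care patients. Provides a
    one-compartment infusion model with exponential inter-individual
    variability, first-order conditional estimation (FOCE) with interaction,
    stepwise covariate model building with likelihood-ratio gates, model
    diagnostics (nonparametric bootstrap, visual predictive checks,
    normalized prediction distribution errors, external-validation
    prediction errors), Monte-Carlo derivation of AUC/MIC-targeted dosing
    tables, and a synthetic neonatal cohort generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
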