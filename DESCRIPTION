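Package: dalbapk
Title: Population Pharmacokinetics and Dosing Simulation for Single-Dose
    Dalbavancin in Prosthetic Joint Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of sparse dalbavancin
    concentration data by the stochastic approximation EM (SAEM) algorithm,
    with a closed-form one- and two-compartment intravenous-infusion
    structural library, importance-sampling likelihood, empirical Bayes
    estimates, shrinkage and relative standard errors. Includes the standard
    model-evaluation suite (non-parametric bootstrap, normalised prediction
    distribution errors, prediction-corrected visual predictive checks,
    goodness-of-fit tables), a forward-inclusion/backward-elimination
    covariate search with renal-function covariate formulas, a Monte Carlo
    probability-of-target-attainment engine over protein-binding and MIC
    grids for fAUC/MIC targets, and a synthetic-cohort generator emulating
    an elderly chronic prosthetic joint infection population given a single
    1,500 mg dalbavancin dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    minpack.lm,
    optparse
Config/testthat/edition: 3
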