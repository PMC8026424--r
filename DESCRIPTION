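Package: ramupk
Title: Population Pharmacokinetic Simulation and Infusion-Rate Safety
    Analysis for Ramucirumab Infusion-Duration Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for model-based evaluation of monoclonal-antibody
    infusion duration, built around ramucirumab. Implements a
    two-compartment population pharmacokinetic simulator with sigmoidal
    time-varying clearance, weight-based dosing across the approved
    regimens, exposure-metric computation (Cmax, Ctrough, AUC over a
    dosing interval), visual predictive checks, and a two-stage
    population parameter-recovery fit. A companion statistical pipeline
    derives per-patient infusion rates, tabulates immediate
    infusion-related reaction incidence by infusion-rate quartile, and
    fits the multivariate logistic model relating infusion rate and
    patient covariates to reaction risk, including the standard-60-minute
    sensitivity analysis. Synthetic-cohort and synthetic-PK-dataset
    generators emulate the pooled clinical-trial data structures so the
    whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
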