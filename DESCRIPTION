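Package: lutadosim
Title: Population Pharmacokinetics and Exposure-Dosimetry Simulation for
    Lu-177 DOTATATE Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (popPK) and exposure-dosimetry
    analysis of Lu-177 DOTATATE radioligand therapy. Implements the closed-form
    two-compartment disposition model with zero-order (infusion) input and
    first-order elimination, population simulation with log-normal
    inter-individual variability, Laplace-approximation maximum-likelihood
    population fitting with empirical Bayes estimates and covariate screening,
    prediction-corrected visual predictive checks, power-law kidney and bone
    marrow dosimetry regression with proportional residual error and BIC model
    comparison, and Monte Carlo virtual-subject and virtual-trial engines for
    threshold-exceedance probabilities and trial-size evaluation. A synthetic
    data module generates adult and adolescent cohorts, longitudinal PK
    datasets and per-organ dosimetry tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    ggplot2,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
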