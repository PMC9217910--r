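Package: alsdbn
Title: Dynamic Bayesian Network Modelling and Simulation of ALS Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns constrained two-slice dynamic Bayesian networks from
    longitudinal ALS clinic-visit data (MiToS functional-domain impairment
    flags, survival, support interventions and demographics), simulates
    disease trajectories forward from a single baseline visit by Monte
    Carlo, and evaluates the resulting prognoses with time-dependent
    AU-ROC, integrated AU-ROC, cumulative-incidence calibration and
    chi-squared goodness of fit. Includes structure learning by
    Max-Min Hill-Climbing with BIC scoring under an available-cases
    treatment of missing values, maximum-a-posteriori parameter
    estimation with Dirichlet smoothing, bootstrap edge-confidence
    analysis, risk-factor stratification, and a synthetic-cohort
    generator for fully in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
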