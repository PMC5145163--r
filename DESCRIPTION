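Package: symptomnet
Title: Stochastic Symptom-Network Dynamics, Stress-Induced Hysteresis, and
    Ising Network Estimation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling a psychiatric disorder as a dynamic network
    of binary symptoms. Provides a stochastic simulator in which each
    symptom switches on with a logistic probability driven by the weighted
    activity of its neighbours, a global connectivity multiplier, and an
    external stress input; deterministic stress-ramp protocols with binned
    hysteresis curves, hysteresis-area and forbidden-zone summaries;
    sliding-window lag-1 autocorrelation as a critical-slowing-down early
    warning indicator; estimation of network weights and thresholds from
    binary cross-sectional data by nodewise L1-regularised logistic
    regression with extended-BIC model selection; and exact and Gibbs
    samplers from the Ising distribution for fully synthetic, reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
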