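Package: vlbwmort
Title: Dynamic Mortality Risk Prediction for Very Low Birth Weight Neonates
Version: 0.1.0
Authors@R:
    person("SEN1500", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scoring, development and validation machinery for staged logistic
    mortality models in very low birth weight (VLBW) neonates: a prenatal
    model, a 24-hours-of-life model and a dynamic during-admission model
    stratified at day 30 of life. Ships the published regression equations and
    severity bands, a pseudo-evolution day expansion with diagnosis
    time-window gating, Kappa-optimal cutoff selection, false-negative-rate
    based risk stratification, and validation statistics (AUC with DeLong
    confidence intervals, Brier score, Cohen kappa, Hosmer-Lemeshow,
    Nagelkerke R squared). Includes a synthetic SEN1500-like cohort generator
    with a known logistic outcome mechanism so that every pipeline stage is
    testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
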