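Package: frailtyflow
Title: Stock-Flow Simulation of Frailty Onset and Progression in an
    Ageing Population
Version: 0.1.0
Authors@R:
    person("frailtyflow", "developers", email = "frailtyflow@example.org",
           role = c("aut", "cre"))
Description: A compartmental (stock-flow) simulation model of frailty
    onset and progression in adults aged 50 and over. The population is
    stratified into 16 subgroups (four age bands crossed with four
    electronic frailty index categories: Fit, Mild, Moderate, Severe)
    and evolves by annual competing flows for death, cohort
    de-registration, ageing to the next band, and irreversible frailty
    progression, with exogenous entries. Includes least-squares
    calibration of constant and time-polynomial flow rates from annual
    cohort observation tables, mean-absolute-percentage-error (MAPE)
    validation against held-out cohorts, cross-cohort rescaling of
    entry/de-registration rates and initial prevalence, national
    scale-up driven by population projections with inflow only at age
    50, and a stochastic synthetic-cohort generator with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
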