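Package: fviiidose
Title: Body-Weight-Metric Dosing Simulations for Factor VIII Prophylaxis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo evaluation of prophylactic factor VIII dosing
    regimens in virtual adult hemophilia A populations. Generates
    BMI-stratified cohorts of virtual patients, computes alternative
    body-size metrics (total, lean, ideal and adjusted body weight),
    samples individual pharmacokinetic parameters from a published
    two-compartment population model with lean-body-weight covariate
    scaling and lognormal between-subject variability, simulates
    steady-state activity-time profiles for every-48-hour and
    Monday-Wednesday-Friday bolus schedules, and titrates doses per kg
    of each weight metric to the minimal value keeping trough activity
    at or above 1 IU/dL in a target fraction of the population, with
    weekly factor consumption as the economic endpoint.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
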