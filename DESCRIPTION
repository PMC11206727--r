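Package: biosimpk
Title: Population Pharmacokinetics of TNF-Inhibitor Biosimilars with
    Dosing-Regimen Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (popPK) analysis of
    subcutaneously administered TNF-inhibitor biosimilars (adalimumab and
    etanercept) in sparse clinical sampling designs. Provides closed-form one-
    and two-compartment concentration-time models with first-order absorption,
    a hierarchical nonlinear mixed-effects model with lognormal between-subject
    variability and combined additive/proportional residual error, deterministic
    Laplace / adaptive Gauss-Hermite maximum-likelihood estimation with
    covariate selection by likelihood-ratio testing and AIC, simulation-based
    model diagnostics (PRED/IPRED, IWRES, PWRES, NPDE with Shapiro-Wilk
    testing), a synthetic-data generator emulating trough-oriented sampling
    schedules, a NONMEM-style CSV reader/writer, and forward simulation of
    alternative dosing intervals against therapeutic windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
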