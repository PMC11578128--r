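Package: lactpk
Title: Lactation Population Pharmacokinetics of Lamivudine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population-pharmacokinetic modelling of maternal plasma to
    breast-milk drug transfer with a one-compartment oral-absorption model
    linked to a milk effect compartment.  Provides closed-form and ODE
    solutions of the structural model, nonlinear mixed-effects estimation by
    Laplace (FOCE-style) approximation with proportional residual error,
    likelihood-ratio testing, stepwise covariate modelling, nonparametric
    bootstrap, conditional weighted residuals, prediction-corrected visual
    predictive checks, infant-exposure calculators (relative infant dose,
    allometric-maturation infant clearance, steady-state infant
    concentration), and a synthetic-study generator emulating the paired
    plasma-milk-infant sampling design of a 35-mother lamivudine lactation
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
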