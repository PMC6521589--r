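Package: enantiopk
Title: Developmental Pharmacokinetics of Chiral Drugs with Systemic
    Enantiomer Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developmental pharmacokinetic (PK) analysis of
    racemic drugs whose enantiomers interconvert systemically, built
    around a two-enantiomer one-compartment model with unidirectional
    R-to-S inversion clearance. Provides closed-form and ODE-based
    simulation of intravenous and oral dosing regimens, per-subject
    nonlinear least-squares estimation with the sequential scheme that
    fixes the inversion clearance from intravenous data before fitting
    oral profiles, non-compartmental analysis (linear-up/log-down AUC,
    terminal slope, absolute bioavailability, multiple-dose accumulation
    ratio), renal-marker clearance models (iohexol GFR, PAH eRPF),
    allometric power-law scaling against body weight, and a synthetic
    cohort generator emulating a four-age-group growing-piglet study of
    racemic ibuprofen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
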