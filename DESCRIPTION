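Package: nrtlle
Title: NRTL Liquid-Liquid Equilibrium Toolkit for Solvent Extraction of
    Fermentation Acids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling liquid-liquid equilibrium (LLE) with the
    Non-Random Two-Liquid (NRTL) activity-coefficient model, aimed at the
    design of solvent-extraction recovery of dilute fermentation products
    such as butyric acid. Provides multicomponent NRTL activity
    coefficients and the reduced Gibbs free energy of mixing, tangent-plane
    phase-stability analysis, an isothermal two-liquid-phase flash, binodal
    curve and tie-line tracing for ternary diagrams, a non-iterative
    tie-line-constrained K-value parameter estimation procedure, a
    steady-state countercurrent multistage extractor simulator with solvent
    performance metrics, annualized recovery-cost arithmetic, a synthetic
    tie-line data generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
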