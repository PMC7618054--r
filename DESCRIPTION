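Package: atosensor
Title: Mechanistic Modelling and Sensitivity Analysis of AtoSC Acetoacetate Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rational design of whole-cell acetoacetate biosensors
    built on the Escherichia coli AtoSC two-component system. Provides a
    mass-action ordinary differential equation model of the AtoS histidine
    kinase / AtoC response regulator phosphorelay with a GFP reporter cascade,
    stiff integration to steady state, dose-response sweeps over the kinase
    autophosphorylation rate (a proxy for acetoacetate concentration), Hill
    transfer-function characterisation (half-maximal dose, dynamic range, fold
    change), a from-scratch Morris elementary-effects global sensitivity screen
    with Campolongo optimal-trajectory selection, and a synthetic
    flow-cytometry data generator (log-normal single-cell fluorescence,
    rainbow-bead calibration to molecules of equivalent fluorophore, median
    summarisation) for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
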