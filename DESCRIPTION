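Package: emip
Title: Desk-Scale Design Workbench for Electropolymerized Molecularly
    Imprinted Polymer Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rational design of electropolymerized molecularly
    imprinted polymer (e-MIP) sensors. Implements a rigid-body Metropolis
    Monte Carlo sampler in the constant-NPT ensemble for template/monomer/
    solvent boxes, extraction and population statistics of first-solvation-
    shell pre-polymerization cavities with a two-stage energy-cutoff funnel,
    classification of tabulated QTAIM bond-critical-point interactions with
    Espinosa binding energies, and the electroanalytical computations used
    to characterise the finished sensor: square-wave voltammetry peak
    extraction, linear calibration with detection limits, Randles-circuit
    fitting of impedance spectra, and polymer film thickness from the
    electropolymerization charge. A synthetic-data module generates every
    input format with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
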