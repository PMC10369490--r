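Package: phrex
Title: Analysis of pH-Replica-Exchange Constant-pH Simulations of
    Membrane-Inserting Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for pH replica-exchange (pHRE)
    constant-pH molecular dynamics of membrane-inserting peptides such as
    pHLIP. Computes signed membrane-insertion depths against a local
    phosphate-surface reference, leaflet half-thickness deformation scans,
    first-interaction-shell censuses (phosphate, choline, water hydrogen
    bonds, arginine salt bridges), insertion-binned titration curves with
    quality-control criteria, Hill fits yielding pKa-versus-depth profiles
    with Bayesian-bootstrap errors, the pH replica-exchange Metropolis
    acceptance rule with a toy ladder simulator, Hill and multiexponential
    fitting of experimental pH-dependence and stopped-flow kinetics data,
    and random-forest attribution of pKa shifts to electrostatic partners.
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
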