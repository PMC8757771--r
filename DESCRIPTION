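Package: gelprint
Title: Printability Prediction for Shear-Thinning Hydrogel Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the complete extrusion-bioprinting printability workflow for
    shear-thinning (power-law) hydrogel inks such as self-assembling peptide
    hydrogels. Fits the Ostwald-de Waele power law to flow-sweep rheology,
    solves fully developed non-Newtonian flow through a syringe-plus-needle
    extrusion train (velocity profile, plug fraction, Rabinowitsch-Mooney wall
    shear stress, pressure drop under three rheological models), computes the
    lead-screw piston force and pressure capacity of a piston-driven extruder,
    screens wall shear stress against a cell-damage threshold, and simulates
    the transient gravity-driven collapse of a printed wood-pile scaffold with
    a plane-strain Kelvin-Voigt finite-element model, with and without a
    sacrificial support bath. Includes seeded synthetic-data generators for
    flow curves and printed-line-width tables so the full pipeline is testable
    without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
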