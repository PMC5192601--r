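Package: plantflux
Title: Multi-Compartment Stoichiometric Modelling of Plant Source-Sink
    Sucrose Translocation
Version: 0.1.0
Authors@R:
    person("plantflux", "developers", email = "plantflux@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of a compartmentalised stoichiometric
    model of a growing C3 plant (source mesophyll, transport phloem, sink
    root).  Provides exact-rational elemental and charge balance checking,
    stoichiometric-matrix topology (degrees of freedom, conserved moieties,
    internal parallel routes, elementary flux modes), flux balance analysis
    with parsimonious and variability variants under light/dark scenario
    presets, and derived energy, redox and proton ledgers that account for
    proton-coupled sucrose translocation from source to sink tissue.
    Includes a programmatically built reduced model of Arabidopsis thaliana
    central carbon and energy metabolism, a synthetic-network generator with
    planted ground truth, and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy, used as linear-programming
    backend through the bundled helper script.
Config/testthat/edition: 3
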