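Package: dacmet
Title: Differential Annotation of Converted Metabolites in Untargeted
    LC-HRMS Plasma Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering and annotating drug- and herb-derived
    converted metabolites (phase-II conjugates and hydrolysis products)
    in plasma from aligned untargeted LC-HRMS feature tables:
    differential peak filtration against pre-dose and mock samples,
    mass-difference conjugation-network construction with
    retention-time-shift windows and calibrant-based source scoring, 34S
    isotopologue and diagnostic neutral-loss evidence, herbal-origin
    attribution, MSI confidence levels, and kinetic time-course
    clustering (half-minimum imputation, auto-scaling, Ward linkage).
    Includes a deterministic synthetic-experiment generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
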