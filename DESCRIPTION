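Package: nanocontact
Title: Quantifying Bacteria-Nanotopography Interactions from FIB-SEM Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ground-truthed pipeline for quantifying physical interactions
    between bacterial cells and nanostructured surfaces from focused ion beam
    scanning electron microscopy (FIB-SEM) slice-and-view stacks. Provides a
    synthetic phantom generator (nanopillar fields, rod and coccus cells,
    imposed penetration/deformation/impedance/rupture interactions, simulated
    acquisition with stage-tilt foreshortening, per-slice drift and noise),
    stack alignment and geometry correction, multi-level segmentation,
    watertight isosurface reconstruction, mesh morphometry (envelope surface
    area, cell volume, penetration and deformation depths, nanopillar tip
    contact areas), an explicit interaction-classification ladder, and
    per-cell morphometric reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
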