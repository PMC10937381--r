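Package: nucfold
Title: Simulation and Analysis of Nucleosome-Resolution Chromatin Folding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse micrococcal-nuclease-based chromosome conformation
    capture (Micro-C) data at nucleosome resolution and to simulate synthetic
    chromatin with known ground truth for validating every analysis stage.
    Includes chimeric ligation-pair classification, dyad shifting and filtering;
    base-pair- and nucleosome-binned contact matrices, pile-ups and
    distance-decay curves; diamond insulation scores with prominence-based
    boundary calling and Li thresholding; MNase-seq dyad coverage, composite
    profiles and linker-length / nucleosome-free-region metrics; and a
    coarse-grained bead model with simulated-annealing 3D reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
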