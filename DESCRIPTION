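Package: MacrocyclePPB
Title: Residue-Level Plasma Protein Binding Prediction for Cyclic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the plasma protein binding rate (%PPB) of cyclic
    peptides from residue-level features. The macrocycle of each peptide is
    decomposed into capped residue substructures, 2D physicochemical
    descriptors are computed for every substructure, and a 1D convolutional
    network with circular convolutions and rotation/translation data
    augmentation regresses the clamped %PPB objective. Includes
    Kennard-Stone train/test splitting, bootstrap-Lasso descriptor
    selection, gradient saliency attribution of residue importance, and a
    synthetic cyclic-peptide generator so the full pipeline is testable
    without proprietary assay data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
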