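Package: mustardQSAR
Title: 2D- and 3D-QSAR Modelling of Dipeptide-Alkylated Nitrogen-Mustard
    Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling
    pipeline for dipeptide-alkylated nitrogen-mustard anti-osteosarcoma
    compounds. Implements the pIC50 activity transform, heuristic stepwise
    multilinear descriptor selection with collinearity control, gene
    expression programming (Karva-notation symbolic regression), CoMSIA-style
    Gaussian similarity-index fields on a lattice around rigidly aligned
    molecules, NIPALS partial least squares with leave-one-out Q2 and optimal
    component selection, contour/field-contribution analysis, external
    validation statistics, and seeded synthetic-data generators for
    parameter-recovery testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
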