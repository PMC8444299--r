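Package: clsnap
Title: Clearance Classification by Combining Descriptor Models and
    Multi-Angle Molecular Snapshot Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary classification of pharmacokinetic clearance (high vs
    low at 1 L/h/kg) from molecular structure by two complementary
    quantitative structure-activity relationship branches and their
    combination.  The descriptor branch filters a numeric descriptor
    table, selects features by permutation importance and fits a
    cross-validated classifier chosen by logloss.  The image branch
    renders each 3D conformer as a set of ball-and-stick snapshots over
    a lattice of x/y/z rotations and trains a small convolutional
    network on the snapshots, aggregating per-image probabilities to a
    per-molecule median.  The two branches are combined as an ensemble
    (probability mean) and as a consensus (agreement subset).  Includes
    Youden-index cutoff selection, a nine-metric evaluation report,
    stratified splitting with PCA chemical-space diagnostics, and a
    seeded synthetic molecule library generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    methods,
    png,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, used through the
    bundled helper script for SMILES handling, descriptors and 3D
    conformer embedding.
Config/testthat/edition: 3
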