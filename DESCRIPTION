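Package: structmatch
Title: Local Structural Comparison of Proteins with User-Defined
    Pseudoatom Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares local three-dimensional arrangements of residues
    between protein structures. Structures are projected into point sets
    ("pseudoatoms") according to a small residue-definition language that
    lets the user choose the level of detail (C-alpha only, side-chain
    centroids, individual chemical groups) and declare which residues or
    residue fragments may be paired. A branch-and-bound search enumerates
    all maximum-size correspondences whose points superimpose below an RMSD
    threshold, using the quaternion method for optimal rigid superposition.
    Includes a database-screening harness that ranks hits by size and RMSD,
    validates them by ligand proximity, and scores rankings by ROC AUC, plus
    a synthetic-structure generator so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
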