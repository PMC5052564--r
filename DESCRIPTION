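Package: glycostruct
Title: Structure-Based Prediction of N- and O-Linked Glycosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts human N- and O-linked glycosylation sites from protein
    three-dimensional structures by combining sequence-derived features (PSSM
    windows, AAindex scales, physicochemical properties, residue conservation)
    with structural features (Shrake-Rupley solvent accessibility, backbone
    dihedrals, residue depth index, epitope log-odds, B-factors) averaged over
    a spatial structure window. Feature selection is performed in two steps:
    linear support-vector-machine weight ranking followed by incremental
    feature selection under repeated cross-validated random-forest AUC. The
    final random-forest classifier supports specificity-calibrated decision
    thresholds for high-confidence proteome screening. Includes a synthetic
    structure/profile generator with planted site labels so the whole pipeline
    can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    ranger,
    Rcpp,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
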