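Package: ddimage
Title: Drug-Drug Interaction Prediction from Structure-Derived Feature Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary drug-drug interactions from chemical structure
    alone. Each drug's SMILES string is parsed into a molecular graph, encoded
    as a hashed circular (Morgan/ECFP-style) fingerprint plus a panel of
    molecular descriptors, rendered as a grayscale feature image, and a pair of
    such images is classified by a shared residual convolutional encoder
    (ResNet18 layout) with a two-logit pair head. Includes a synthetic dataset
    generator with planted interaction rules, a five-way feature ablation
    harness, a logistic-regression baseline, and the six standard evaluation
    metrics (precision, recall, F1, AUPR, AUC, accuracy). The SMILES parser,
    fingerprint hashing, descriptor calculators and the neural network are
    implemented in base R (BLAS-backed), so the whole pipeline runs offline
    with no external toolkit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
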