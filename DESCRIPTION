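Package: rfscreen
Title: Ligand-Based Virtual Screening with Hybrid Depth/Breadth Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: From-scratch random forest classifier for ligand-based virtual
    screening of compound libraries. Decision trees are grown iteratively
    (non-recursively) from a frontier that operates as a stack during an
    initial depth-first phase and as a queue beyond a node-count crossover
    threshold given by the regression 3705 + 0.0577*n + 21.84*f. Includes a
    179-descriptor molecular featurization (drug-likeness panel, Burden-matrix
    eigenvalue descriptors, pharmacophore-pair fingerprint bits) for SDF and
    SMILES input, batched screening of arbitrarily large compound streams, an
    evaluation metric panel (recall, precision, F-score, ROC area, accuracy),
    a synthetic bioassay generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
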