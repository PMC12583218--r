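Package: heterodti
Title: Drug-Target Interaction Prediction on Heterogeneous Graphs with
    Knowledge-Based Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions by message passing over a
    heterogeneous graph built from chemical fingerprint similarity, protein
    sequence similarity and known interactions. An attention-weighted
    multi-relational graph-convolutional encoder is trained with a
    feature-reconstruction loss, a margin-ranking knowledge-graph
    regularizer and a positive-unlabeled interaction loss with
    reliability-based negative sampling and importance weighting. Includes
    dataset-specific network adaptation, k-fold and cold-start evaluation
    (AUROC, AUPR, F1, precision-at-k), Gaussian-process Bayesian
    hyperparameter optimization with expected improvement, and a synthetic
    data generator with planted low-rank interaction structure for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
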