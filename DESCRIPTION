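Package: drugseqr
Title: Sequence-Based Druggable-Protein Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting protein druggability from amino-acid sequence.
    Implements evolutionary-profile feature encoders over PSI-BLAST position
    specific scoring matrices (dipeptide composition, k-separated bigrams and
    filtered row-sum descriptors, concatenated to 1200 dimensions), a pluggable
    protein-language-model embedder contract with 320-dimensional mean-pooled
    representations, contact-map extraction and a length-sorted fine-tuning
    harness, three from-scratch deep classifiers (a multilayer perceptron, a
    capsule network with dynamic routing, and a bidirectional LSTM), a compact
    decoder-transformer that classifies raw tokenized sequences end to end, and
    a stratified evaluation protocol with five-fold cross-validation, six
    confusion-matrix metrics, ROC/AUC, classical machine-learning baselines and
    attribution-group aggregation. A deterministic synthetic benchmark generator
    makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
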