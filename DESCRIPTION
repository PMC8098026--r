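Package: dtimap
Title: Substructure Interaction Maps for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions from SMILES and protein
    sequences via explicit substructure interaction maps. Provides a
    frequent-consecutive-subsequence (FCS) miner that learns a byte-pair-style
    substructure vocabulary from sequence corpora, transformer encoders that
    embed substructure sequences with content plus positional embeddings, a
    pairwise drug-by-protein interaction map aggregated by a small
    convolutional layer and decoded to an interaction probability, a full
    training and evaluation protocol (Adam, validation-based model selection,
    ROC-AUC / PR-AUC / best-F1 thresholding), a synthetic motif-rule data
    generator for download-free testing, and interaction-map interpretability
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
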