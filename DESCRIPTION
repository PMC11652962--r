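Package: deepathnet
Title: Pathway-Guided Transformer Models for Multiomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements DeePathNet, a transformer-based model that encodes
    per-pathway multiomic gene features (mutation, copy number, RNA,
    protein) into pathway embeddings, models pathway-pathway interactions
    with multi-head self-attention, and predicts drug response (multi-drug
    IC50 regression with missing entries) or cancer type and subtype
    (classification). Includes readers for delimited omic matrices, GMT
    gene sets and target tables; an explanation layer (epsilon-rule
    layer-wise relevance propagation at the pathway level and permutation
    Shapley attribution at the gene-by-modality level); an evaluation
    harness (repeated cross-validation, regression and classification
    metrics, paired tests, confusion matrices, per-drug summaries); a
    synthetic multiomic generator with known causal pathway structure; and
    ablation controls (size-matched random pathway rewiring, plain
    multilayer perceptron, down-sampling curves). The network, its
    training loop and the attribution rules are implemented in base R
    matrix code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
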