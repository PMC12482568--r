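Package: histofuse
Title: Dual-Branch CNN-Transformer Fusion for Histopathology Tile
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A configurable implementation of a parallel residual-CNN plus
    Vision-Transformer classifier for histopathology tiles. The CNN branch adds
    squeeze-and-excitation channel recalibration after its final stage; the
    Transformer branch taps [CLS] tokens at several depths and averages them; a
    token-aligned multimodal attention module fuses the two embeddings before a
    softmax head. Includes the surrounding pipeline: grid and sliding-window
    patch extraction, stratified image-level splitting, patient-grouped
    stratified k-fold planning with leakage audits, augmentation policies, an
    AdamW training loop with cosine warmup scheduling and early stopping,
    patch-to-image majority voting, classification metrics with one-vs-rest
    ROC AUC, paired t-test / Cohen's d run comparisons, fused multi-layer
    Grad-CAM explanations scored against lesion masks, and a deterministic
    synthetic histology-tile generator so everything is testable at desk scale
    on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
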