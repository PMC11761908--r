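Package: lwunet
Title: Lightweight Depthwise-Separable U-Net Pipeline for Multimodal Breast-Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact, dependency-light pipeline for classifying breast lesions
    (benign vs malignant) in multimodal imaging (mammography and ultrasound).
    Implements Box-Cox intensity normalization, a nine-layer depthwise-separable
    convolution encoder/decoder classifier with hand-written forward and backward
    passes, a stratified k-fold cross-validation training harness with
    confusion-matrix metrics and fold aggregation, GAN-side computations
    (adaptive instance normalization, logistic adversarial losses,
    feature-matching loss, gradient penalty, Frechet distance between image
    embeddings) exercised by a desk-scale mini-GAN, and a seeded synthetic
    lesion-image generator so every stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    e1071
Config/testthat/edition: 3
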