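Package: meshtex
Title: Adaptive Multiscale Local Mesh Ternary Patterns for Lesion Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based classification toolkit for oral-lesion photographs.
    Implements a three-stage enhancement chain (contrast-limited adaptive
    histogram equalization, gamma correction, Laplacian sharpening), the
    Adaptive Multiscale Local Mesh Ternary Pattern (AM-LMTP) descriptor with a
    per-pixel adaptive threshold and two-scale histogram features, Grey Wolf
    Optimization for classifier hyperparameter tuning, and a stratified
    evaluation protocol with precision, recall, accuracy and one-vs-rest ROC
    curves. Ships a seeded synthetic-texture generator so the whole pipeline
    is testable without any clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    ranger,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
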