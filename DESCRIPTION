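Package: retinopatch
Title: Patch-Based Deep-Feature Engineering for Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature-engineering pipeline for grading diabetic retinopathy
    from colour fundus photographs. Images are resized to a 256x256 canvas,
    divided into four quadrants and eight orientation-dependent rectangular
    patches, and each of the nine inputs (main image plus patches) is mapped
    to a deep-feature vector by a pluggable embedding backend (pretrained
    DenseNet201 in production, a deterministic linear stub for offline
    testing). Concatenated features are min-max normalized, weighted by a
    regularized neighborhood component analysis implemented from scratch,
    reduced to the top-k columns, and classified by a cubic (degree-3
    polynomial kernel) support vector machine under stratified 10-fold
    cross-validation and 80:20 hold-out protocols, with a six-metric panel
    (accuracy, unweighted average recall and precision, macro F1, Cohen's
    kappa, geometric mean of recalls). A synthetic fundus-image generator
    and planted-feature matrices make every stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    caret,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
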