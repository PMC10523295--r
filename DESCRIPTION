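Package: leukoscope
Title: White Blood Cell Image Segmentation, Classification and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computer-aided pipeline for classifying single-cell blood smear
    images into the four common leukocyte types (eosinophil, lymphocyte,
    monocyte, neutrophil). Provides HSV colour-threshold segmentation of
    stained cells with morphological cleanup, a configurable
    dense-connectivity convolutional classifier with a replaceable transfer
    head, a from-scratch one-cycle / cyclical learning-rate training engine
    with a learning-rate range test, a full multiclass evaluation suite
    (confusion matrix, precision/recall/F1, macro and micro averages, Cohen's
    kappa, one-vs-rest ROC/AUC), and a deterministic synthetic blood-smear
    generator with ground-truth masks so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
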