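Package: liporad
Title: Radiomics, Batch Harmonisation and Classifier Benchmarking for
    Lipomatous Tumour MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A benign-versus-malignant lipomatous tumour imaging workflow:
    3D radiomic feature extraction (92 features spanning shape, histogram,
    GLCM, GLRLM, GLSZM, NGTDM and Gabor families, with equal-probability
    gray-level quantization), parametric empirical-Bayes ComBat batch-effect
    harmonisation, benchmarking of four classifiers under patient-grouped
    cross-validation with DeLong and McNemar comparisons, and a small
    from-scratch convolutional network baseline. A synthetic multi-batch
    phantom cohort generator with known ground truth makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    e1071,
    ranger,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    optparse
Config/testthat/edition: 3
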