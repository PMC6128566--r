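Package: dermwave
Title: Wavelet-Based Decision Support for Melanocytic Lesion Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support classification of dermoscopic melanocytic-lesion
    images into excise versus do-not-excise. Implements Chan-Vese level-set
    segmentation and standardised preprocessing to a canonical 512x512 frame,
    a 1152-dimensional wavelet sub-band statistics feature bank (six
    decomposition levels, four sub-bands, RGB plus luminance channels, twelve
    statistics per band), ReliefF feature ranking, PCA feature extraction with
    a strict train-fit/test-transform contract, RBF-kernel support-vector
    classification with probabilistic output (random forest and penalised
    logistic regression as comparators), and repeated stratified k-fold and
    leave-one-out cross-validation with ROC and diagnostic-odds-ratio
    summaries. Includes seeded generators for synthetic lesion images and
    synthetic feature tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    randomForest,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
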