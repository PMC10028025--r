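Package: brushmorph
Title: Morphometric Profiling of Cell Clusters on Bile Duct Brushing Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated morphological analysis of epithelial cell clusters on
    digitized bile duct brushing cytology specimens. Provides preprocessing of
    cluster crops (background removal, artifact filtering, histogram
    equalization, local illumination normalization), automatic cluster
    detection on slide-scale images, watershed nuclear segmentation, a
    536-dimensional hand-crafted feature bank (windowed Haralick and CoLlAGe
    co-occurrence statistics, Gabor and Law's filter responses, and nuclear
    shape descriptors), univariate and minimum-redundancy-maximum-relevance
    feature selection, and a class-imbalance-aware multi-expert classifier
    evaluated by repeated patient-level cross-validation. A synthetic cluster
    generator with ground-truth nuclear masks makes the whole pipeline
    testable without clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    rpart,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    jsonlite,
    optparse,
    png,
    tiff,
    withr
Config/testthat/edition: 3
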