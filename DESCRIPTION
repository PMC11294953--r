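Package: GliomaRadiomics
Title: Radiomics-Based Prediction of IDH Mutation Status in Glioma from
    Multicontrast MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-stage radiomics framework for predicting isocitrate
    dehydrogenase (IDH) mutation status in glioma from coregistered
    multicontrast MRI (T1, postcontrast T1, T2, T2-FLAIR). Constructs
    whole-tumor and nonenhancing-tumor regions of interest from labeled
    segmentations, derives twelve filtered images per sequence (Laplacian
    of Gaussian at four scales, four undecimated wavelet subbands, and
    four monotone intensity transforms), extracts 1197 radiomics features
    per region per sequence across seven feature classes (shape,
    first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM), selects features by
    Boruta shadow-feature testing aggregated over multiple balanced
    subsets, trains a class-balanced undersampling ensemble of random
    forest or gradient-boosting classifiers combined by probability
    averaging, and evaluates predictions with ROC/AUC and DeLong
    confidence intervals. Includes a synthetic cohort generator so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
    ranger,
    xgboost,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
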