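Package: noduleTLR
Title: Adaptive Cross-Domain Transfer-Learning Radiomics for Solitary Pulmonary Solid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes lung granulomatous nodules from solid lung adenocarcinoma on
    nodule-centred CT patches with an adaptive cross-domain transfer-learning pipeline:
    a pretrained source network, a target network trained under a meta-network-gated
    source-feature-matching constraint, 3904 pooled convolutional transfer-learning
    features per patient, a sparse Bayesian extreme learning machine signature (TLS),
    sliced-Wasserstein ranking of candidate source domains, and a sparse-Bayes-LASSO
    fusion of the signature with clinical factors and subjective CT findings (TLRM).
    Ships a synthetic cohort and source-domain generator so the whole pipeline runs at
    desk scale, plus the full evaluation stack (DeLong, IDI, Hosmer-Lemeshow,
    decision curves, stratified analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    RNifti,
    png,
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    glmnet,
    EBImage,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
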