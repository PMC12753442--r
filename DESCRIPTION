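Package: lnmfusion
Title: Multi-Modal Contrastive Learning for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a multi-modal contrastive learning model
    for preoperative prediction of lymph node metastasis in cervical cancer.
    Three encoders -- a residual convolutional backbone for CT-like images,
    one for ultrasound-like images, and a two-layer perceptron for clinical
    indicators -- are aligned with a three-way InfoNCE contrastive loss and
    fused by concatenation into a binary classifier trained under
    class-imbalance-aware weighted sampling. Includes a synthetic cohort
    generator with per-modality planted signal, clinical preprocessing
    (inflammation and nutrition indices, tumor-marker threshold flags,
    min-max normalization), confusion-matrix and ROC/AUC evaluation with an
    ablation report, and a baseline-characteristics table module
    (normality-gated summaries, Pearson chi-square, Fisher exact, pooled t,
    Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
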