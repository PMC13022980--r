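Package: retiKAN
Title: Diabetic Retinopathy Severity Grading with Convolutional
    Kolmogorov-Arnold Networks and Improved Whale Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable toolkit for five-grade diabetic
    retinopathy severity classification from fundus photographs. Provides a
    synthetic graded-fundus image generator with EyePACS-style class
    imbalance, CLAHE-based preprocessing and label-preserving augmentation,
    a ShuffleNet-V2-style convolutional backbone with a LeViT-style
    attention block, a convolutional Kolmogorov-Arnold (cKAN) classification
    head built on clamped cubic B-spline function banks with a regularized
    training objective, an Improved Whale Optimization (IWO) metaheuristic
    (chaotic tent-map initialization, nonlinear convergence factor, cosine
    inertia weight, Cauchy mutation, optimal-based feedback) for
    FLOPs-aware hyperparameter search, and stratified five-fold
    cross-validation with multiclass metrics (MCC, Cohen's kappa,
    AUROC/AUPRC) and fold-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nnet,
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
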