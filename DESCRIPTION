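Package: fedus
Title: Federated Learning Simulation for Ultrasound-Based Steatosis Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Config-driven simulation of cross-site federated learning for
    binary hepatic steatosis classification (grade S0 versus S1 or higher)
    from B-mode-like grayscale ultrasound images. Provides a synthetic
    two-site cohort generator with grade-dependent echogenicity and
    correlated Rayleigh speckle, four non-IID data partitioning strategies
    (Dirichlet class skew, quantity-based class skew, Dirichlet quantity
    skew, source-based), a class-imbalance scenario builder with a local
    homogeneity mixture, weighted cosine-similarity heterogeneity metrics,
    an in-process federated training loop with FedAvg, FedAvgM, FedYogi and
    FedProx server updates over a small convolutional network trained with
    focal loss and Adam, and the evaluation statistics used in diagnostic
    imaging studies: ROC AUC, confusion metrics, patient-level jackknife
    confidence intervals and the DeLong test for correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
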