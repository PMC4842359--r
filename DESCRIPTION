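Package: ckainit
Title: Supervised Neural-Network Pretraining by Centered Kernel Alignment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a linear projection of a feature table by maximizing the
    centered kernel alignment (CKA) between a Mahalanobis-Gaussian feature
    kernel and a class-label kernel, and uses the projection to initialize
    the first layer of a feedforward softmax classifier. Includes the
    per-feature relevance analysis induced by the projection, unsupervised
    initialization baselines (PCA and a single-hidden-layer autoencoder),
    multiclass evaluation (accuracy, class-wise recall, one-vs-rest ROC/AUC),
    stratified cross-validation tuning of the hidden-layer size, and a seeded
    generator of morphometric-feature-like datasets with a normal-control /
    mild-cognitive-impairment / Alzheimer's class structure for fully
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
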