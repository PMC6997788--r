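Package: hergcaps
Title: Capsule Network Classifiers for hERG Channel Blockade
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary classification of small molecules as hERG potassium
    channel blockers or nonblockers using capsule networks. Implements two
    architectures: a convolution-capsule network (Conv-CapsNet) whose
    feature extractor is a 1-d convolution followed by fully connected
    layers, and an RBM-capsule network (RBM-CapsNet) whose feature
    extractor is a stack of two restricted Boltzmann machines pretrained
    by contrastive divergence. Both feed a capsule head trained end-to-end
    with dynamic routing and a margin loss on capsule lengths. Molecules
    are characterized by 166 MACCS fingerprint bits plus 13 physicochemical
    descriptors, min-max scaled on the training set. Includes a stratified
    cross-validation and early-stopping harness, confusion-matrix metrics
    (accuracy, sensitivity, specificity, Matthews correlation coefficient),
    rank-based ROC/AUC, a synthetic data generator emulating the
    fingerprint-plus-descriptor feature layout, and a command-line
    interface for featurization, training, evaluation, and prediction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
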