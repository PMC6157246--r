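Package: sirnadeep
Title: Two-Modality Deep Architecture for siRNA Silencing Efficacy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the silencing efficacy of small interfering RNAs (siRNAs)
    from two feature modalities: one-hot encoded target-site sequence context
    with flanking nucleotides, and twenty nearest-neighbor thermodynamic
    descriptors of the siRNA duplex. A bank of convolutional motif detectors
    with joint max/average pooling is merged with the thermodynamic vector,
    batch-normalized, and passed through a sigmoid dense layer to a sigmoid
    output trained by full-batch gradient descent on mean-squared error.
    Includes seeded synthetic-data generation with a planted flank motif and a
    duplex end-asymmetry signal, ten-fold cross-validation, ROC/AUC and Pearson
    correlation evaluation, hyperparameter scan harnesses, model
    serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    pROC,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
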