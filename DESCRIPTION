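Package: methCascade
Title: Grid-Searched Multilayer Dynamic Ensembles for DNA N4-Methylcytosine
    Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts DNA N4-methylcytosine (4mC) sites from fixed-length
    (41 bp) sequence windows centred on a cytosine. Sequences are tokenized
    into overlapping k-mers, embedded with a continuous bag-of-words (CBOW)
    word2vec model trained in compiled code, and classified by an ensemble
    of small one-dimensional convolutional networks whose member weights are
    chosen by exhaustive grid search at every layer of a dynamic
    self-training cascade: correctly classified test items are promoted into
    the training set and the misclassified remainder forms the next layer's
    test set, until a layer adds no correct calls. Includes dataset
    balancing, greedy identity-based redundancy filtering, stratified
    splitting, a confusion-matrix metric suite with ROC/AUC, a synthetic
    planted-motif dataset generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'MethSeqSet-methods.R'
    'RcppExports.R'
    'sequences-io.R'
    'features.R'
    'cnn.R'
    'reference-learner.R'
    'ensemble.R'
    'methCascade-package.R'
    'metrics.R'
    'synthetic.R'
    'pipeline.R'
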