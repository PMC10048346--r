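#' @include utils.R
NULL

#' Sequences of a dataset
#'
#' @param x A [MethSeqSet-class] object.
#' @return A [Biostrings::DNAStringSet] of the stored sequences.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Sequence length shared by all records
#'
#' @param x A [MethSeqSet-class] object.
#' @return Integer window length (nt), `NA` for an empty set.
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' Vocabulary of a k-mer embedding
#'
#' @param x A [KmerEmbedding-class] object.
#' @return Character vector of in-vocabulary k-mers.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Fit a binary classifier
#'
#' Trains a classifier from scratch on a feature tensor. The input object is
#' an untrained (or previously trained) prototype; a new, fitted object is
#' returned.
#'
#' @param object A classifier extending `BinaryClassifier`.
#' @param x Numeric feature array of shape `(n, positions, dims)` as produced
#'   by [embedSequences()].
#' @param y Binary labels (0/1), length `n`.
#' @param ... Passed to methods.
#' @return The fitted classifier object.
#' @export
setGeneric("fitClassifier", function(object, x, y, ...)
  standardGeneric("fitClassifier"))

#' Predict class-1 probabilities
#'
#' @param object A fitted classifier.
#' @param x Feature array of shape `(n, positions, dims)`.
#' @return Numeric vector of length `n` with probabilities in `[0, 1]`.
#' @export
setGeneric("predictProba", function(object, x)
  standardGeneric("predictProba"))

#' Replace the RNG seed of a classifier prototype
#'
#' @param object A classifier.
#' @param seed Integer seed.
#' @return The classifier with its training seed replaced.
#' @export
setGeneric("reseed", function(object, seed) standardGeneric("reseed"))

#' Cumulative total accuracy of a multilayer cascade
#'
#' The cascade's headline statistic: the number of test records correctly
#' classified at any layer, divided by the size of the *initial* test set,
#' \deqn{TA = \sum_i (TP_i + TN_i) / S_{Test}.}
#' Records left unresolved when the loop stops count as errors.
#'
#' @param x Per-layer correct counts: a numeric vector of `TP + TN` per
#'   layer, a layer-ledger `data.frame` with `TP` and `TN` columns, or an
#'   [MLDSResult-class] object.
#' @param initialTestSize Size of the initial test set (ignored for
#'   `MLDSResult`, which carries its own).
#' @return Total accuracy as a fraction in `[0, 1]`.
#' @examples
#' totalAccuracy(c(110, 39), 156)   # 149/156
#' @export
setGeneric("totalAccuracy", function(x, initialTestSize)
  standardGeneric("totalAccuracy"))

#' Layer-by-layer ledger of a cascade run
#'
#' @param x An [MLDSResult-class] object.
#' @return A `data.frame` with one row per executed layer: sizes, confusion
#'   counts, ensemble weights, layer and cumulative accuracy.
#' @export
setGeneric("layerLedger", function(x) standardGeneric("layerLedger"))
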