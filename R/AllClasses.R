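#' @include AllGenerics.R
NULL

#' Labeled fixed-length DNA sequence set
#'
#' The central data container: equal-width DNA sequences over the strict
#' A/C/G/T alphabet with a binary label per record (1 = 4mC-positive,
#' 0 = non-4mC). Extends [S4Vectors::Annotated] so parse metadata
#' (e.g. rejected-record counts) travels with the object.
#'
#' @slot sequences A [Biostrings::DNAStringSet]; all widths equal.
#' @slot labels Integer vector of 0/1, parallel to `sequences`.
#'
#' @seealso [MethSeqSet()], [readFastaDataset()], [generateDataset()]
#' @export
setClass("MethSeqSet",
  contains = "Annotated",
  representation(sequences = "DNAStringSet", labels = "integer")
)

setValidity("MethSeqSet", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels)) {
    msg <- c(msg, "lengths of 'sequences' and 'labels' differ")
  }
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0 or 1")
  }
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) != 1L) {
      msg <- c(msg, "all sequences must share one length")
    }
    af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    if (any(af[, "other"] > 0)) {
      msg <- c(msg, "sequences must contain only A/C/G/T")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethSeqSet
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet]
#'   (lower-case input is normalized to upper case).
#' @param labels Binary labels (0/1), one per sequence.
#' @param ids Optional record identifiers; defaults to existing names or
#'   `seq1, seq2, ...`.
#' @param requireCenterC If `TRUE` and the shared length is odd, every
#'   sequence must carry `C` at the central position (the putative 4mC
#'   site); violations are an error.
#' @return A validated [MethSeqSet-class].
#' @examples
#' ds <- MethSeqSet(c("ACGTC", "TTCAG"), labels = c(1, 0))
#' seqLength(ds)
#' @export
MethSeqSet <- function(sequences, labels, ids = NULL, requireCenterC = FALSE) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  labels <- as.integer(labels)
  if (!is.null(ids)) names(sequences) <- ids
  if (is.null(names(sequences)) && length(sequences)) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  obj <- methods::new("MethSeqSet", sequences = sequences, labels = labels)
  if (requireCenterC && length(sequences)) {
    L <- seqLength(obj)
    if (L %% 2L == 1L) {
      centre <- (L + 1L) %/% 2L
      base <- as.character(Biostrings::subseq(sequences, centre, centre))
      if (any(base != "C")) {
        stop("centered-cytosine check failed for record(s): ",
             paste(utils::head(names(sequences)[base != "C"], 5L),
                   collapse = ", "), call. = FALSE)
      }
    }
  }
  obj
}

#' Trained k-mer embedding model
#'
#' Maps every in-vocabulary k-mer to a dense real vector learned by the CBOW
#' word2vec objective (predict a token from its flanking context). Tokens
#' whose corpus count fell below `min_count` are out of vocabulary.
#'
#' @slot vectors Numeric matrix, one row per vocabulary k-mer (rownames),
#'   `vector_size` columns.
#' @slot k Integer k-mer width.
#' @slot params The [embeddingParams()] list used for training.
#' @seealso [trainEmbedding()], [embedSequences()]
#' @export
setClass("KmerEmbedding",
  representation(vectors = "matrix", k = "integer", params = "list")
)

setValidity("KmerEmbedding", function(object) {
  if (is.null(rownames(object@vectors))) return("vectors must have rownames")
  if (any(nchar(rownames(object@vectors)) != object@k)) {
    return("all vocabulary entries must have width k")
  }
  TRUE
})

#' Confusion-matrix counts
#'
#' Holds the four counts of a binary confusion matrix. In the field's
#' R-notation the class totals are R+ = TP + FN (positives investigated) and
#' R- = TN + FP (negatives investigated); the error cells are the false
#' negatives (R-+) and false positives (R+-).
#'
#' @slot TP,TN,FP,FN Non-negative integer counts.
#' @seealso [confusionCounts()], [computeMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", TN = "integer", FP = "integer",
                 FN = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L)) {
    return("TP, TN, FP, FN must be single non-negative integers")
  }
  TRUE
})

#' @describeIn ConfusionCounts-class Constructor.
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `ConfusionCounts` object.
#' @examples
#' confusionCounts(TP = 226, TN = 222, FP = 9, FN = 5)
#' @export
confusionCounts <- function(TP, TN, FP, FN) {
  methods::new("ConfusionCounts",
               TP = .assertCount(TP, "TP", positive = FALSE),
               TN = .assertCount(TN, "TN", positive = FALSE),
               FP = .assertCount(FP, "FP", positive = FALSE),
               FN = .assertCount(FN, "FN", positive = FALSE))
}

#' Virtual parent for probabilistic binary classifiers
#'
#' The classifier contract used throughout the ensemble engine: a prototype
#' object is trained with [fitClassifier()] and scored with
#' [predictProba()], which returns one class-1 probability per record.
#' Prediction on a fitted object is deterministic (dropout and other
#' train-time stochasticity are inference-time off).
#'
#' @export
setClass("BinaryClassifier", representation("VIRTUAL"))

#' One-dimensional convolutional classifier
#'
#' A small 1-D CNN over k-mer embedding matrices: unpadded stride-1
#' convolutions with ReLU after each, one dropout layer, flatten, a single
#' dense unit and a sigmoid output, trained by Adam on binary cross-entropy.
#'
#' @slot config Validated architecture/training configuration, see
#'   [cnnConfig()].
#' @slot fit Internal list of trained parameters (empty until fitted).
#' @seealso [cnnClassifier()], [cnnPreset()]
#' @export
setClass("ConvNetClassifier",
  contains = "BinaryClassifier",
  representation(config = "list", fit = "list")
)

#' Pooled ridge-logistic reference classifier
#'
#' Fast deterministic stand-in obeying the same contract as the CNNs: token
#' vectors are mean-pooled over positions and a ridge-regularized logistic
#' regression is fitted by iteratively reweighted least squares. Used for
#' quick pipeline checks and as the learner in property tests.
#'
#' @slot lambda Ridge penalty.
#' @slot seed Integer seed (kept for contract symmetry; the fit itself is
#'   deterministic).
#' @slot fit Internal list with the fitted coefficients.
#' @seealso [referenceLearner()]
#' @export
setClass("PooledLogisticClassifier",
  contains = "BinaryClassifier",
  representation(lambda = "numeric", seed = "integer", fit = "list")
)

#' Result of a multilayer dynamic cascade run
#'
#' @slot layers Ledger `data.frame`, one row per executed layer: `layer`,
#'   `train_size`, `test_size`, `TP`, `TN`, `FP`, `FN`, weight columns
#'   `w1..wm`, `layer_accuracy`, `cumulative_accuracy`.
#' @slot initialTestSize Size of the layer-1 test set (the denominator of
#'   the total-accuracy statistic).
#' @slot totalAccuracy Total accuracy as a fraction.
#' @slot assignments Per initial-test-record `data.frame`: `id`, `label`,
#'   `predicted` (final predicted label), `layer` (layer at which the record
#'   was resolved correctly; `NA` if never), `prob_layer1` (layer-1 ensemble
#'   probability, used for ROC).
#' @slot mode Character, `"faithful"` or `"honest"` weight selection.
#' @seealso [runMLDS()], [totalAccuracy()], [layerLedger()]
#' @export
setClass("MLDSResult",
  representation(layers = "data.frame", initialTestSize = "integer",
                 totalAccuracy = "numeric", assignments = "data.frame",
                 mode = "character")
)
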