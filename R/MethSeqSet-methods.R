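#' @include AllClasses.R
NULL

#' @describeIn MethSeqSet-class Number of records.
#' @param x,object A `MethSeqSet`.
#' @export
setMethod("length", "MethSeqSet", function(x) length(x@sequences))

#' @describeIn MethSeqSet-class Record identifiers.
#' @export
setMethod("names", "MethSeqSet", function(x) names(x@sequences))

#' @describeIn MethSeqSet-class The stored sequences.
#' @export
setMethod("sequences", "MethSeqSet", function(x) x@sequences)

#' @describeIn MethSeqSet-class Binary labels (1 = 4mC-positive).
#' @param ... Ignored.
#' @export
setMethod("labels", "MethSeqSet", function(object, ...) object@labels)

#' @describeIn MethSeqSet-class Shared sequence length (nt).
#' @export
setMethod("seqLength", "MethSeqSet", function(x) {
  if (!length(x@sequences)) return(NA_integer_)
  Biostrings::width(x@sequences)[1L]
})

#' @describeIn MethSeqSet-class Subset records, preserving order of `i`.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @export
setMethod("[", "MethSeqSet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, sequences = x@sequences[i], labels = x@labels[i])
})

#' Combine two datasets
#'
#' @param x,y `MethSeqSet` objects with equal sequence length.
#' @return The concatenated `MethSeqSet` (records of `x` first).
#' @export
combineDatasets <- function(x, y) {
  stopifnot(methods::is(x, "MethSeqSet"), methods::is(y, "MethSeqSet"))
  if (length(x) && length(y) && seqLength(x) != seqLength(y)) {
    stop("cannot combine datasets with different sequence lengths",
         call. = FALSE)
  }
  methods::initialize(x, sequences = c(x@sequences, y@sequences),
                      labels = c(x@labels, y@labels))
}

setMethod("show", "MethSeqSet", function(object) {
  n <- length(object)
  cat(sprintf("MethSeqSet with %d record%s (%d positive, %d negative)\n",
              n, if (n == 1L) "" else "s",
              sum(object@labels == 1L), sum(object@labels == 0L)))
  if (n) cat(sprintf("  sequence length: %d nt\n", seqLength(object)))
  invisible(object)
})

#' @describeIn KmerEmbedding-class In-vocabulary k-mers.
#' @param x A `KmerEmbedding`.
#' @export
setMethod("vocabulary", "KmerEmbedding", function(x) rownames(x@vectors))

#' @describeIn KmerEmbedding-class Dimensions of the vector table
#'   (vocabulary size, vector size).
#' @export
setMethod("dim", "KmerEmbedding", function(x) dim(x@vectors))

setMethod("show", "KmerEmbedding", function(object) {
  cat(sprintf("KmerEmbedding: %d %d-mers -> %d-d vectors (CBOW)\n",
              nrow(object@vectors), object@k, ncol(object@vectors)))
  invisible(object)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
              object@TP, object@TN, object@FP, object@FN))
  invisible(object)
})

setMethod("show", "MLDSResult", function(object) {
  cat(sprintf(
    "MLDSResult: %d layer%s, initial test size %d, total accuracy %.4f\n",
    nrow(object@layers), if (nrow(object@layers) == 1L) "" else "s",
    object@initialTestSize, object@totalAccuracy))
  print(object@layers, row.names = FALSE)
  invisible(object)
})

#' @describeIn MLDSResult-class The per-layer ledger.
#' @param x An `MLDSResult`.
#' @export
setMethod("layerLedger", "MLDSResult", function(x) x@layers)
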