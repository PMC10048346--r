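#' @include reference-learner.R
NULL

#' Weights-normalized ensemble probabilities
#'
#' Combines per-learner probabilities as a weighted mean normalized by the
#' weight sum, so the ensemble probability stays in \[0, 1\] and scaling all
#' weights by a positive constant changes nothing.
#'
#' @param probs Numeric matrix (records x learners) or list of equal-length
#'   probability vectors.
#' @param weights Non-negative weights, one per learner, not all zero.
#' @return Numeric vector of ensemble probabilities.
#' @examples
#' weightedAveragePredict(cbind(0.8, 0.2, 0.6), c(0.3, 0.5, 0.2))  # 0.46
#' @export
weightedAveragePredict <- function(probs, weights) {
  P <- .probMatrix(probs)
  weights <- as.numeric(weights)
  if (length(weights) != ncol(P)) {
    stop("need one weight per learner (", ncol(P), "), got ",
         length(weights), call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  as.vector(P %*% weights) / sum(weights)
}

.probMatrix <- function(probs) {
  if (is.list(probs)) {
    len <- lengths(probs)
    if (length(unique(len)) > 1L) {
      stop("learners report different record counts", call. = FALSE)
    }
    probs <- do.call(cbind, probs)
  }
  P <- as.matrix(probs)
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  P
}

# All weight tuples on the grid {0, step, ..., 1}^m in lexicographic order,
# all-zero tuple removed.
.weightGrid <- function(m, step) {
  vals <- round(seq(0, 1, by = step), 10)
  W <- as.matrix(do.call(expand.grid,
                         c(rep(list(vals), m), KEEP.OUT.ATTRS = FALSE)))
  dimnames(W) <- NULL
  ord <- do.call(order, lapply(seq_len(m), function(j) W[, j]))
  W <- W[ord, , drop = FALSE]
  W[rowSums(W) > 0, , drop = FALSE]
}

#' Exhaustive grid search over ensemble weights
#'
#' Evaluates every weight tuple on the grid `{0, gridStep, ..., 1}` per
#' learner (the all-zero tuple excluded) and returns the tuple maximizing
#' the accuracy of the thresholded ensemble probabilities against the
#' labels. Ties are broken toward the lexicographically smallest tuple, so
#' the search is fully deterministic.
#'
#' @param probs Records x learners probability matrix (or list of vectors).
#' @param labels Binary labels (0/1).
#' @param gridStep Grid spacing in (0, 1].
#' @param threshold Decision threshold on the ensemble probability.
#' @return `list(weights = , accuracy = )`.
#' @export
gridSearchWeights <- function(probs, labels, gridStep = 0.1,
                              threshold = 0.5) {
  P <- .probMatrix(probs)
  if (nrow(P) == 0L) stop("empty test set", call. = FALSE)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(P), all(labels %in% c(0L, 1L)))
  .assertFraction(gridStep, "gridStep", open = FALSE)
  if (gridStep <= 0) stop("'gridStep' must be positive", call. = FALSE)
  W <- .weightGrid(ncol(P), gridStep)
  Pens <- sweep(P %*% t(W), 2L, rowSums(W), "/")
  acc <- colMeans((Pens >= threshold) == (labels == 1L))
  j <- which.max(acc)  # first maximum = lexicographically smallest tuple
  list(weights = as.numeric(W[j, ]), accuracy = acc[[j]])
}

#' Threshold, count, and partition a scored test set
#'
#' Predicts class 1 where the ensemble probability is at least `threshold`,
#' tallies the confusion counts against the true labels, and splits the
#' record indices into the correctly and incorrectly classified sets — the
#' routing step of the dynamic cascade.
#'
#' @param probs Ensemble probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return `list(counts = ConfusionCounts, correct = , incorrect = )` with
#'   index vectors partitioning `seq_along(labels)`.
#' @export
classifyAndPartition <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% c(0L, 1L)))
  pred <- as.integer(probs >= threshold)
  counts <- confusionCounts(TP = sum(pred == 1L & labels == 1L),
                            TN = sum(pred == 0L & labels == 0L),
                            FP = sum(pred == 1L & labels == 0L),
                            FN = sum(pred == 0L & labels == 1L))
  list(counts = counts,
       correct = which(pred == labels),
       incorrect = which(pred != labels),
       predicted = pred)
}

.bindRows3d <- function(a, b) {
  if (!dim(a)[1L]) return(b)
  if (!dim(b)[1L]) return(a)
  out <- array(0, c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

#' Run the grid-searched multilayer dynamic cascade
#'
#' The core procedure. Per layer: (a) every base learner is re-initialized
#' and fitted from scratch on the current training set; (b) ensemble weights
#' are chosen by exhaustive grid search; (c) the current test set is
#' classified and partitioned; (d) correctly classified records join the
#' training set (with their true labels) and the misclassified remainder
#' becomes the next layer's test set. The loop stops when a layer classifies
#' nothing correctly (TP + TN = 0), the test set is exhausted, or the layer
#' cap is reached; records still unresolved then count as errors. Total
#' accuracy is the cumulative correct count over the *initial* test size.
#'
#' In the default `"faithful"` mode the grid search scores candidate weight
#' tuples against the true test labels, exactly as the cascade is defined —
#' note this leaks evaluation labels into weight selection (routing must use
#' true labels either way). `"honest"` mode instead selects weights on an
#' inner validation split carved from the training set; routing is
#' unchanged.
#'
#' @param train,test Disjoint [MethSeqSet-class] objects; `test` non-empty.
#' @param learners List of classifier prototypes (default: the three
#'   convolutional presets from [cnnPresets()]).
#' @param k k-mer width for tokenization.
#' @param embedding Optional pre-trained [KmerEmbedding-class]; when `NULL`
#'   a CBOW model is trained on the union of `train` and `test` (the
#'   embedding corpus convention for this method).
#' @param embedParams [embeddingParams()] used when `embedding` is `NULL`.
#' @param gridStep,threshold Grid spacing and decision threshold.
#' @param maxLayers Safety cap on the number of layers.
#' @param mode `"faithful"` or `"honest"` weight selection (see above).
#' @param ensemble `"WAE"` (grid-searched weights) or `"AE"` (equal
#'   weights).
#' @param seed Master seed; per-layer learner seeds are derived from it.
#' @param verbose Print a progress line per layer.
#' @return An [MLDSResult-class].
#' @export
runMLDS <- function(train, test, learners = NULL, k = 3L, embedding = NULL,
                    embedParams = embeddingParams(), gridStep = 0.1,
                    threshold = 0.5, maxLayers = 20L,
                    mode = c("faithful", "honest"),
                    ensemble = c("WAE", "AE"), seed = 1L, verbose = FALSE) {
  stopifnot(methods::is(train, "MethSeqSet"), methods::is(test, "MethSeqSet"))
  mode <- match.arg(mode)
  ensemble <- match.arg(ensemble)
  if (!length(test)) stop("initial test set is empty", call. = FALSE)
  if (!length(train)) stop("training set is empty", call. = FALSE)
  if (any(names(test) %in% names(train))) {
    stop("train and test sets are not disjoint", call. = FALSE)
  }
  if (is.null(learners)) learners <- cnnPresets(seed = seed)
  stopifnot(length(learners) >= 1L,
            all(vapply(learners, methods::is, TRUE, "BinaryClassifier")))
  if (is.null(embedding)) {
    ep <- embedParams
    ep$seed <- .deriveSeed(seed, 5L)
    class(ep) <- "embeddingParams"
    embedding <- trainEmbedding(buildCorpus(combineDatasets(train, test), k),
                                ep)
  }
  xTr <- embedSequences(train, embedding, k)
  xTe <- embedSequences(test, embedding, k)
  yTr <- labels(train)
  yTe <- labels(test)
  m <- length(learners)
  nTest0 <- length(test)
  origPos <- seq_len(nTest0)   # positions of current test in the initial set
  resolvedLayer <- rep(NA_integer_, nTest0)
  finalPred <- rep(NA_integer_, nTest0)
  probLayer1 <- rep(NA_real_, nTest0)
  rows <- list()

  for (i in seq_len(maxLayers)) {
    fitted <- lapply(seq_len(m), function(j) {
      fitClassifier(reseed(learners[[j]], .deriveSeed(seed, i, j)),
                    xTr, yTr)
    })
    P <- vapply(fitted, predictProba, numeric(dim(xTe)[1L]), x = xTe)
    P <- matrix(P, nrow = dim(xTe)[1L], ncol = m)
    if (ensemble == "AE") {
      w <- rep(1, m)
    } else if (mode == "faithful") {
      w <- gridSearchWeights(P, yTe, gridStep, threshold)$weights
    } else {
      w <- .honestWeights(learners, xTr, yTr, gridStep, threshold,
                          .deriveSeed(seed, i, m + 1L))
    }
    pEns <- weightedAveragePredict(P, w)
    part <- classifyAndPartition(pEns, yTe, threshold)
    cc <- part$counts
    if (i == 1L) probLayer1 <- pEns
    finalPred[origPos] <- part$predicted
    resolvedLayer[origPos[part$correct]] <- i
    rows[[i]] <- data.frame(
      layer = i, train_size = length(yTr), test_size = length(yTe),
      TP = cc@TP, TN = cc@TN, FP = cc@FP, FN = cc@FN,
      matrix(w, 1L, m, dimnames = list(NULL, paste0("w", seq_len(m)))),
      layer_accuracy = (cc@TP + cc@TN) / length(yTe))
    if (verbose) {
      message(sprintf(
        "layer %d: train %d test %d TP %d TN %d FP %d FN %d (w: %s)",
        i, length(yTr), length(yTe), cc@TP, cc@TN, cc@FP, cc@FN,
        paste(w, collapse = ", ")))
    }
    if (cc@TP + cc@TN == 0L) break
    xTr <- .bindRows3d(xTr, xTe[part$correct, , , drop = FALSE])
    yTr <- c(yTr, yTe[part$correct])
    xTe <- xTe[part$incorrect, , , drop = FALSE]
    yTe <- yTe[part$incorrect]
    origPos <- origPos[part$incorrect]
    if (!length(yTe)) break
  }

  layers <- do.call(rbind, rows)
  layers$cumulative_accuracy <- cumsum(layers$TP + layers$TN) / nTest0
  ta <- sum(layers$TP + layers$TN) / nTest0
  assignments <- data.frame(
    id = names(test), label = labels(test), predicted = finalPred,
    layer = resolvedLayer, prob_layer1 = probLayer1,
    stringsAsFactors = FALSE)
  methods::new("MLDSResult", layers = layers,
               initialTestSize = nTest0, totalAccuracy = ta,
               assignments = assignments, mode = mode)
}

# Weight selection without looking at test labels: carve a stratified
# validation subset from the training pool, fit clones on the remainder,
# and grid-search on the held-out predictions.
.honestWeights <- function(learners, xTr, yTr, gridStep, threshold, seed) {
  n <- length(yTr)
  valIdx <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(lab) {
      idx <- which(yTr == lab)
      sample(idx, max(1L, floor(0.2 * length(idx))))
    }))
  })
  fitIdx <- setdiff(seq_len(n), valIdx)
  fitted <- lapply(seq_along(learners), function(j) {
    fitClassifier(reseed(learners[[j]], .deriveSeed(seed, j)),
                  xTr[fitIdx, , , drop = FALSE], yTr[fitIdx])
  })
  P <- vapply(fitted, predictProba, numeric(length(valIdx)),
              x = xTr[valIdx, , , drop = FALSE])
  P <- matrix(P, nrow = length(valIdx), ncol = length(learners))
  gridSearchWeights(P, yTr[valIdx], gridStep, threshold)$weights
}

#' @describeIn totalAccuracy From per-layer correct counts.
#' @export
setMethod("totalAccuracy", signature("numeric", "numeric"),
          function(x, initialTestSize) {
  initialTestSize <- .assertCount(initialTestSize, "initialTestSize")
  if (any(x < 0)) stop("per-layer correct counts must be non-negative",
                       call. = FALSE)
  s <- sum(x)
  if (s > initialTestSize) {
    stop("internal-consistency error: correct counts (", s,
         ") exceed the initial test size (", initialTestSize, ")",
         call. = FALSE)
  }
  s / initialTestSize
})

#' @describeIn totalAccuracy From a layer ledger with `TP`/`TN` columns.
#' @export
setMethod("totalAccuracy", signature("data.frame", "numeric"),
          function(x, initialTestSize) {
  stopifnot(all(c("TP", "TN") %in% names(x)))
  totalAccuracy(as.numeric(x$TP + x$TN), initialTestSize)
})

#' @describeIn totalAccuracy From a cascade result (recomputed from its
#'   ledger).
#' @export
setMethod("totalAccuracy", signature("MLDSResult", "missing"),
          function(x, initialTestSize) {
  totalAccuracy(x@layers, as.numeric(x@initialTestSize))
})

#' Write a cascade ledger as TSV
#'
#' One row per layer with sizes, confusion counts, the selected weights
#' (comma-joined), and layer/cumulative accuracies.
#'
#' @param x An [MLDSResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLedger <- function(x, path) {
  stopifnot(methods::is(x, "MLDSResult"))
  df <- x@layers
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  df$weights <- apply(df[wcols], 1L, paste, collapse = ",")
  df <- df[c("layer", "train_size", "test_size", "TP", "TN", "FP", "FN",
             "weights", "layer_accuracy", "cumulative_accuracy")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
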