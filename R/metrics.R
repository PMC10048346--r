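#' @include ensemble.R
NULL

#' Confusion-matrix metric suite
#'
#' Standard definitions on the four counts: accuracy `(TP+TN)/(R+ + R-)`,
#' precision `TP/(TP+FP)`, recall (TPR) `TP/R+`, FPR `FP/R-`, TNR
#' (specificity) `TN/R-`, FNR `FN/R+`, where `R+ = TP+FN` and `R- = TN+FP`
#' are the class totals. Values are full-precision fractions; format at
#' report time. A metric whose denominator is zero is reported as `NA`
#' (undefined) with a warning, never silently as 0.
#'
#' @param counts A [ConfusionCounts-class] (see [confusionCounts()]).
#' @return Named numeric vector with elements `accuracy`, `precision`,
#'   `recall`, `fpr`, `tnr`, `fnr`.
#' @examples
#' m <- computeMetrics(confusionCounts(TP = 226, TN = 222, FP = 9, FN = 5))
#' round(100 * m, 2)
#' @export
computeMetrics <- function(counts) {
  stopifnot(methods::is(counts, "ConfusionCounts"))
  TP <- counts@TP; TN <- counts@TN; FP <- counts@FP; FN <- counts@FN
  rpos <- TP + FN
  rneg <- TN + FP
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = safe(TP + TN, rpos + rneg, "accuracy"),
    precision = safe(TP, TP + FP, "precision"),
    recall = safe(TP, rpos, "recall"),
    fpr = safe(FP, rneg, "FPR"),
    tnr = safe(TN, rneg, "TNR"),
    fnr = safe(FN, rpos, "FNR"))
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC from the sorted unique scores used as thresholds (predict
#' positive where `score >= threshold`) and integrates it by the trapezoid
#' rule. Tied scores move along the curve jointly, so the AUC equals the
#' probability that a random positive outscores a random negative, with
#' half credit for ties.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels with both classes present.
#' @return `list(points = data.frame(threshold, fpr, tpr), auc = )`.
#' @export
rocCurveAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1L
  last <- cumsum(rle(s)$lengths)  # last index of each unique score
  tpr <- cumsum(pos)[last] / nPos
  fpr <- cumsum(!pos)[last] / nNeg
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1L) + points$tpr[-1L]) / 2)
  list(points = points, auc = auc)
}

#' Aggregate confusion counts of a cascade run
#'
#' Every initial test record is counted once: at the layer that resolved it
#' correctly, or with its final (incorrect) prediction if the loop stopped
#' first.
#'
#' @param x An [MLDSResult-class].
#' @return A [ConfusionCounts-class].
#' @export
cascadeConfusion <- function(x) {
  stopifnot(methods::is(x, "MLDSResult"))
  a <- x@assignments
  confusionCounts(TP = sum(a$predicted == 1L & a$label == 1L),
                  TN = sum(a$predicted == 0L & a$label == 0L),
                  FP = sum(a$predicted == 1L & a$label == 0L),
                  FN = sum(a$predicted == 0L & a$label == 1L))
}

#' Balanced accuracy
#'
#' `(TPR + TNR) / 2`; reported alongside the trapezoidal AUC because for a
#' single hard classification the two coincide numerically.
#'
#' @param counts A [ConfusionCounts-class].
#' @return Fraction in `[0, 1]` (or `NA` if a class total is zero).
#' @export
balancedAccuracy <- function(counts) {
  m <- computeMetrics(counts)
  unname((m["recall"] + m["tnr"]) / 2)
}
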