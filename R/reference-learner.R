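#' @include cnn.R
NULL

#' Fast deterministic reference learner
#'
#' Mean-pools the token vectors of each record over positions and fits a
#' ridge-regularized logistic regression by iteratively reweighted least
#' squares. Obeys the same [fitClassifier()] / [predictProba()] contract as
#' the convolutional learners, at a fraction of the cost, which makes it the
#' learner of choice for pipeline smoke tests and property checks. The fit
#' is fully deterministic; the seed is carried only for contract symmetry.
#'
#' @param seed Integer seed.
#' @param lambda Ridge penalty on the non-intercept coefficients.
#' @return A [PooledLogisticClassifier-class] prototype.
#' @export
referenceLearner <- function(seed = 1L, lambda = 1e-3) {
  stopifnot(is.numeric(lambda), lambda > 0)
  methods::new("PooledLogisticClassifier", lambda = lambda,
               seed = as.integer(seed), fit = list())
}

.meanPool <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  colMeans(aperm(x, c(2L, 1L, 3L)))  # (n, d)
}

#' @describeIn PooledLogisticClassifier-class Ridge-logistic IRLS fit on
#'   mean-pooled features.
#' @param object,x,y,... See [fitClassifier()].
#' @export
setMethod("fitClassifier", "PooledLogisticClassifier",
          function(object, x, y, ...) {
  y <- as.numeric(y)
  X <- cbind(1, .meanPool(x))
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  pen <- c(0, rep(object@lambda, ncol(X) - 1L))
  beta <- numeric(ncol(X))
  for (it in seq_len(50L)) {
    p <- stats::plogis(as.vector(X %*% beta))
    w <- pmax(p * (1 - p), 1e-6)
    H <- crossprod(X * w, X) + diag(pen)
    g <- crossprod(X, y - p) - pen * beta
    delta <- solve(H, g)
    beta <- beta + as.vector(delta)
    if (max(abs(delta)) < 1e-10) break
  }
  methods::initialize(object, fit = list(beta = beta))
})

#' @describeIn PooledLogisticClassifier-class Deterministic probabilities.
#' @export
setMethod("predictProba", "PooledLogisticClassifier", function(object, x) {
  if (!length(object@fit)) stop("classifier is not fitted", call. = FALSE)
  stats::plogis(as.vector(cbind(1, .meanPool(x)) %*% object@fit$beta))
})

#' @describeIn PooledLogisticClassifier-class Replace the seed (a no-op for
#'   the deterministic fit, kept for contract symmetry).
#' @param seed Integer seed.
#' @export
setMethod("reseed", "PooledLogisticClassifier", function(object, seed) {
  methods::initialize(object, seed = as.integer(seed), fit = list())
})
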