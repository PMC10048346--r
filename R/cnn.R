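#' @include features.R
NULL

# ---- internal tensor plumbing -------------------------------------------
# A batch (n, T, d) is held as an n x (T*d) matrix in position-major layout:
# column (p-1)*d + j holds channel j of position p. Unpadded stride-1
# convolutions then become one big matrix product on an im2col expansion.

.toPosMajor <- function(x) {
  dm <- dim(x)
  matrix(aperm(x, c(1L, 3L, 2L)), dm[1L], dm[2L] * dm[3L])
}

.convForward <- function(Xm, n, d, kernel, W, b) {
  Tlen <- ncol(Xm) %/% d
  T1 <- Tlen - kernel + 1L
  f <- ncol(W)
  Xcol <- matrix(0, n * T1, kernel * d)
  for (p in seq_len(T1)) {
    Xcol[((p - 1L) * n + 1L):(p * n), ] <-
      Xm[, ((p - 1L) * d + 1L):((p + kernel - 1L) * d), drop = FALSE]
  }
  Z <- Xcol %*% W + rep(b, each = n * T1)
  mask <- Z > 0
  A <- Z * mask
  Out <- matrix(0, n, T1 * f)
  for (p in seq_len(T1)) {
    Out[, ((p - 1L) * f + 1L):(p * f)] <-
      A[((p - 1L) * n + 1L):(p * n), , drop = FALSE]
  }
  list(Out = Out, Xcol = Xcol, mask = mask, T1 = T1)
}

.convBackward <- function(dOut, cache, W, n, d, kernel) {
  T1 <- cache$T1
  f <- ncol(W)
  dA <- matrix(0, n * T1, f)
  for (p in seq_len(T1)) {
    dA[((p - 1L) * n + 1L):(p * n), ] <-
      dOut[, ((p - 1L) * f + 1L):(p * f), drop = FALSE]
  }
  dA <- dA * cache$mask
  dW <- crossprod(cache$Xcol, dA)
  db <- colSums(dA)
  dXcol <- dA %*% t(W)
  Tlen <- T1 + kernel - 1L
  dXm <- matrix(0, n, Tlen * d)
  for (p in seq_len(T1)) {
    cols <- ((p - 1L) * d + 1L):((p + kernel - 1L) * d)
    dXm[, cols] <- dXm[, cols] +
      dXcol[((p - 1L) * n + 1L):(p * n), , drop = FALSE]
  }
  list(dW = dW, db = db, dXm = dXm)
}

# He-initialized parameters; errors if a layer's kernel exceeds its input
# length. Returns list(W1, b1, ..., wd, bd) plus the flattened width.
.cnnInit <- function(cfg, Tlen, d) {
  nl <- length(cfg$filters)
  params <- list()
  Tcur <- Tlen
  dcur <- d
  for (l in seq_len(nl)) {
    k <- cfg$kernels[l]
    f <- cfg$filters[l]
    if (k > Tcur) {
      stop("shape error: kernel ", k, " exceeds input length ", Tcur,
           " at convolution layer ", l, call. = FALSE)
    }
    params[[paste0("W", l)]] <-
      matrix(stats::rnorm(k * dcur * f, sd = sqrt(2 / (k * dcur))),
             k * dcur, f)
    params[[paste0("b", l)]] <- numeric(f)
    Tcur <- Tcur - k + 1L
    dcur <- f
  }
  flat <- Tcur * dcur
  params$wd <- matrix(stats::rnorm(flat, sd = sqrt(2 / (flat + 1))), flat, 1L)
  params$bd <- 0
  attr(params, "flatSize") <- flat
  params
}

.cnnForwardConvs <- function(params, Xm, n, d, kernels) {
  caches <- vector("list", length(kernels))
  dcur <- d
  for (l in seq_along(kernels)) {
    caches[[l]] <- .convForward(Xm, n, dcur, kernels[l],
                                params[[paste0("W", l)]],
                                params[[paste0("b", l)]])
    Xm <- caches[[l]]$Out
    dcur <- ncol(params[[paste0("W", l)]])
  }
  list(flat = Xm, caches = caches)
}

# Binary cross-entropy loss and analytic gradients for a full forward +
# backward pass. `dropMask` (same shape as the flattened layer, already
# inverted-scaled) is NULL at inference/gradient-check time.
.cnnLossGrad <- function(params, Xm, y, d, kernels, dropMask = NULL) {
  n <- nrow(Xm)
  fw <- .cnnForwardConvs(params, Xm, n, d, kernels)
  flat <- fw$flat
  if (!is.null(dropMask)) flat <- flat * dropMask
  z <- flat %*% params$wd + params$bd
  p <- stats::plogis(as.vector(z))
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dz <- matrix((p - y) / n, n, 1L)
  grads <- list()
  grads$wd <- crossprod(flat, dz)
  grads$bd <- sum(dz)
  dflat <- dz %*% t(params$wd)
  if (!is.null(dropMask)) dflat <- dflat * dropMask
  dcurs <- c(d, head(vapply(seq_along(kernels), function(l)
    ncol(params[[paste0("W", l)]]), 0L), -1L))
  dOut <- dflat
  for (l in rev(seq_along(kernels))) {
    bk <- .convBackward(dOut, fw$caches[[l]], params[[paste0("W", l)]],
                        n, dcurs[l], kernels[l])
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("b", l)]] <- bk$db
    dOut <- bk$dXm
  }
  list(loss = loss, grads = grads, probs = p)
}

# ---- public configuration ------------------------------------------------

#' Configure a 1-D convolutional classifier
#'
#' Architectures follow the standard search space for this class of model:
#' up to five stride-1 convolution layers with filter counts from
#' \{16, 32, 42, 64\} and kernel widths from \{3, 5, 7, 9\}, a single
#' dropout layer before the dense sigmoid output. `checkRanges = FALSE`
#' lifts the filter/kernel whitelist (used e.g. for tiny nets in numerical
#' checks); the structural constraints always apply.
#'
#' @param filters Integer vector, filter count per convolution layer.
#' @param kernels Integer vector, kernel width per convolution layer.
#' @param dropout Dropout probability in (0, 1), applied to the flattened
#'   features at train time only.
#' @param epochs,batchSize,learningRate Adam training controls.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param checkRanges Enforce the filter/kernel whitelist.
#' @return A validated config list of class `cnnConfig`.
#' @export
cnnConfig <- function(filters, kernels, dropout, epochs = 20L,
                      batchSize = 32L, learningRate = 1e-3, seed = 1L,
                      checkRanges = TRUE) {
  filters <- as.integer(filters)
  kernels <- as.integer(kernels)
  if (length(filters) != length(kernels) || length(filters) < 1L ||
      length(filters) > 5L) {
    stop("'filters' and 'kernels' must have equal length in 1..5",
         call. = FALSE)
  }
  if (checkRanges) {
    if (!all(filters %in% c(16L, 32L, 42L, 64L))) {
      stop("filter counts must come from {16, 32, 42, 64}", call. = FALSE)
    }
    if (!all(kernels %in% c(3L, 5L, 7L, 9L))) {
      stop("kernel widths must come from {3, 5, 7, 9}", call. = FALSE)
    }
  }
  if (!is.numeric(dropout) || length(dropout) != 1L || dropout <= 0 ||
      dropout >= 1) {
    stop("'dropout' must lie strictly inside (0, 1)", call. = FALSE)
  }
  cfg <- list(filters = filters, kernels = kernels, dropout = dropout,
              epochs = .assertCount(epochs, "epochs"),
              batchSize = .assertCount(batchSize, "batchSize"),
              learningRate = learningRate, seed = as.integer(seed))
  if (!is.numeric(learningRate) || learningRate <= 0) {
    stop("'learningRate' must be positive", call. = FALSE)
  }
  class(cfg) <- "cnnConfig"
  cfg
}

#' The three standard base-learner presets
#'
#' `M1` = conv(16,3) -> conv(32,5), dropout 0.5; `M2` = conv(32,5) ->
#' conv(42,7), dropout 0.3; `M3` = conv(42,7) -> conv(64,9), dropout 0.6;
#' each followed by dense(1) and a sigmoid.
#'
#' @param name `"M1"`, `"M2"` or `"M3"`.
#' @param ... Training controls passed to [cnnConfig()] (`epochs`,
#'   `batchSize`, `learningRate`, `seed`).
#' @return A [ConvNetClassifier-class] prototype.
#' @export
cnnPreset <- function(name = c("M1", "M2", "M3"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    M1 = list(filters = c(16L, 32L), kernels = c(3L, 5L), dropout = 0.5),
    M2 = list(filters = c(32L, 42L), kernels = c(5L, 7L), dropout = 0.3),
    M3 = list(filters = c(42L, 64L), kernels = c(7L, 9L), dropout = 0.6))
  cnnClassifier(do.call(cnnConfig, c(spec, list(...))))
}

#' @rdname cnnPreset
#' @return `cnnPresets()`: list of the three preset classifiers.
#' @export
cnnPresets <- function(...) {
  lapply(c("M1", "M2", "M3"), cnnPreset, ...)
}

#' Build a convolutional classifier from a config
#'
#' @param config A [cnnConfig()] object.
#' @return An untrained [ConvNetClassifier-class].
#' @export
cnnClassifier <- function(config) {
  stopifnot(inherits(config, "cnnConfig"))
  methods::new("ConvNetClassifier", config = unclass(config), fit = list())
}

# ---- classifier contract -------------------------------------------------

#' @describeIn ConvNetClassifier-class Train from scratch by Adam on binary
#'   cross-entropy; all randomness (init, shuffling, dropout) flows from the
#'   config seed, so a fixed seed reproduces the fit exactly.
#' @param object,x,y,... See [fitClassifier()].
#' @export
setMethod("fitClassifier", "ConvNetClassifier", function(object, x, y, ...) {
  cfg <- object@config
  dm <- dim(x)
  if (length(dm) != 3L) stop("'x' must be a (n, positions, dims) array",
                             call. = FALSE)
  n <- dm[1L]; Tlen <- dm[2L]; d <- dm[3L]
  y <- as.numeric(y)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  lr <- cfg$learningRate
  withr::with_seed(cfg$seed, {
    params <- .cnnInit(cfg, Tlen, d)
    flatSize <- attr(params, "flatSize")
    mAdam <- lapply(params, function(p) p * 0)
    vAdam <- mAdam
    step <- 0L
    for (e in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
        Xm <- .toPosMajor(x[idx, , , drop = FALSE])
        keep <- 1 - cfg$dropout
        dropMask <- matrix(
          (stats::runif(length(idx) * flatSize) >= cfg$dropout) / keep,
          length(idx), flatSize)
        g <- .cnnLossGrad(params, Xm, y[idx], d, cfg$kernels, dropMask)
        step <- step + 1L
        corr <- sqrt(1 - beta2 ^ step) / (1 - beta1 ^ step)
        for (nm in names(params)) {
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g$grads[[nm]]
          vAdam[[nm]] <- beta2 * vAdam[[nm]] +
            (1 - beta2) * g$grads[[nm]] ^ 2
          params[[nm]] <- params[[nm]] -
            lr * corr * mAdam[[nm]] / (sqrt(vAdam[[nm]]) + adamEps)
        }
      }
    }
    methods::initialize(object, fit = list(
      params = params, Tlen = Tlen, d = d, flatSize = flatSize))
  })
})

#' @describeIn ConvNetClassifier-class Deterministic inference (dropout
#'   off); repeated calls on the same fitted object agree exactly.
#' @export
setMethod("predictProba", "ConvNetClassifier", function(object, x) {
  if (!length(object@fit)) stop("classifier is not fitted", call. = FALSE)
  dm <- dim(x)
  if (length(dm) != 3L || dm[2L] != object@fit$Tlen ||
      dm[3L] != object@fit$d) {
    stop("shape error: expected (n, ", object@fit$Tlen, ", ",
         object@fit$d, ") features", call. = FALSE)
  }
  params <- object@fit$params
  kernels <- object@config$kernels
  n <- dm[1L]
  out <- numeric(n)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1024L))
  for (ch in chunks) {
    Xm <- .toPosMajor(x[ch, , , drop = FALSE])
    fw <- .cnnForwardConvs(params, Xm, length(ch), dm[3L], kernels)
    out[ch] <- stats::plogis(as.vector(fw$flat %*% params$wd + params$bd))
  }
  out
})

#' @describeIn ConvNetClassifier-class Replace the training seed.
#' @param seed Integer seed.
#' @export
setMethod("reseed", "ConvNetClassifier", function(object, seed) {
  cfg <- object@config
  cfg$seed <- as.integer(seed)
  methods::initialize(object, config = cfg, fit = list())
})
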