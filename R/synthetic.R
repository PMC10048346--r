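#' @include metrics.R
NULL

#' Default planted motif
#'
#' A sharply peaked position weight matrix (dominant base probability 0.91)
#' of width 6 with consensus `TGCAGT`. Sharp columns give near-complete
#' class separability at `motifStrength = 1`; soften them (or lower the
#' strength) to emulate weaker signals.
#'
#' @param width Motif width (consensus is recycled/truncated to fit).
#' @param dominant Probability of the consensus base at each position.
#' @return A 4 x `width` matrix with rows `A`, `C`, `G`, `T`, columns
#'   summing to 1.
#' @export
defaultMotif <- function(width = 6L, dominant = 0.91) {
  width <- .assertCount(width, "width")
  .assertFraction(dominant, "dominant")
  consensus <- rep_len(c("T", "G", "C", "A", "G", "T"), width)
  bases <- c("A", "C", "G", "T")
  pwm <- matrix((1 - dominant) / 3, 4L, width, dimnames = list(bases, NULL))
  for (j in seq_len(width)) pwm[consensus[j], j] <- dominant
  pwm
}

#' Specification for a synthetic planted-motif dataset
#'
#' Describes a labeled set of fixed-length DNA windows with a central
#' cytosine in *both* classes (a 4mC site is a methylated C; the negative
#' class carries the same unmethylated C) and a position-weight-matrix
#' motif planted immediately 3' of the centre in positive records. The
#' `motifStrength` mixing fraction is the separability dial: 1 plants the
#' motif in every positive, 0 makes the classes i.i.d. background.
#'
#' @param nPos,nNeg Record counts per class.
#' @param seqLength Odd window length (nt).
#' @param motif PWM over A/C/G/T (rows) by position (columns).
#' @param motifStrength Probability that a positive record carries the
#'   motif.
#' @param background Per-base sampling frequencies (A, C, G, T).
#' @param seed Integer seed.
#' @return A validated spec of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nPos, nNeg, seqLength = 41L,
                          motif = defaultMotif(), motifStrength = 1,
                          background = c(A = 0.25, C = 0.25, G = 0.25,
                                         T = 0.25),
                          seed = 1L) {
  nPos <- .assertCount(nPos, "nPos")
  nNeg <- .assertCount(nNeg, "nNeg")
  seqLength <- .assertCount(seqLength, "seqLength")
  if (seqLength %% 2L == 0L) {
    stop("'seqLength' must be odd (central 4mC site)", call. = FALSE)
  }
  .assertFraction(motifStrength, "motifStrength", open = FALSE)
  stopifnot(is.matrix(motif), nrow(motif) == 4L)
  if (any(abs(colSums(motif) - 1) > 1e-8)) {
    stop("motif columns must each sum to 1", call. = FALSE)
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8) {
    stop("'background' must be four frequencies summing to 1",
         call. = FALSE)
  }
  centre <- (seqLength + 1L) %/% 2L
  if (centre + ncol(motif) > seqLength) {
    stop("motif (width ", ncol(motif), ") is wider than the 3' flank (",
         seqLength - centre, " nt)", call. = FALSE)
  }
  structure(list(nPos = nPos, nNeg = nNeg, seqLength = seqLength,
                 motif = motif, motifStrength = motifStrength,
                 background = unname(background),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate a synthetic labeled dataset
#'
#' Samples background sequences per the spec, forces the central cytosine in
#' every record, and plants the motif in the window immediately 3' of the
#' centre in (a `motifStrength` fraction of) positive records. Fully seeded:
#' the same spec yields byte-identical FASTA output.
#'
#' @param spec A [syntheticSpec()].
#' @return A [MethSeqSet-class] with positives first.
#' @examples
#' ds <- generateDataset(syntheticSpec(nPos = 5, nNeg = 5, seed = 42))
#' ds
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  bases <- c("A", "C", "G", "T")
  n <- spec$nPos + spec$nNeg
  L <- spec$seqLength
  centre <- (L + 1L) %/% 2L
  withr::with_seed(spec$seed, {
    m <- matrix(sample(bases, n * L, replace = TRUE, prob = spec$background),
                n, L)
    m[, centre] <- "C"
    planted <- c(stats::runif(spec$nPos) < spec$motifStrength,
                 rep(FALSE, spec$nNeg))
    idx <- which(planted)
    for (j in seq_len(ncol(spec$motif))) {
      m[idx, centre + j] <- sample(bases, length(idx), replace = TRUE,
                                   prob = spec$motif[, j])
    }
  })
  seqs <- apply(m, 1L, paste, collapse = "")
  ids <- c(sprintf("pos_%05d", seq_len(spec$nPos)),
           sprintf("neg_%05d", seq_len(spec$nNeg)))
  MethSeqSet(seqs, labels = rep(c(1L, 0L), c(spec$nPos, spec$nNeg)),
             ids = ids, requireCenterC = TRUE)
}
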