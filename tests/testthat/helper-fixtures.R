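# Shared fixtures, all built in code at test time.

writeFastaFixture <- function(seqs, ids = paste0("s", seq_along(seqs)),
                              path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

randomDna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# A fixture whose classes a linear pooled model separates almost perfectly:
# wide, nearly deterministic motif.
strongSpec <- function(nPos, nNeg, seed = 1L, ...) {
  syntheticSpec(nPos = nPos, nNeg = nNeg, seed = seed,
                motif = defaultMotif(width = 10L, dominant = 0.97), ...)
}

referenceTrio <- function(seed = 1L) {
  lapply(1:3, function(j) referenceLearner(seed = seed + j,
                                           lambda = 10 ^ -j))
}

fastEmbedding <- function(ds, k = 3L, seed = 1L, dim = 16L) {
  trainEmbedding(buildCorpus(ds, k),
                 embeddingParams(vectorSize = dim, epochs = 4L,
                                 minCount = 1L, seed = seed))
}

# Independent greedy-filter oracle: quadratic, direct transcription of the
# keep rule.
greedyFilterOracle <- function(seqs, labs, threshold) {
  keep <- logical(length(seqs))
  chars <- strsplit(seqs, "")
  for (i in seq_along(seqs)) {
    prior <- which(keep & labs == labs[i])
    ok <- TRUE
    for (j in prior) {
      if (mean(chars[[i]] == chars[[j]]) >= threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  keep
}

# Independent exhaustive weight-search oracle: plain loops, lexicographic
# tie-break toward the smallest tuple.
gridSearchOracle <- function(P, labels, step, threshold = 0.5) {
  vals <- round(seq(0, 1, by = step), 10)
  m <- ncol(P)
  grid <- expand.grid(rep(list(vals), m), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[do.call(order, as.data.frame(grid)), , drop = FALSE])
  best <- NULL
  bestAcc <- -1
  for (r in seq_len(nrow(grid))) {
    w <- grid[r, ]
    if (sum(w) == 0) next
    p <- as.vector(P %*% w) / sum(w)
    acc <- mean((p >= threshold) == (labels == 1))
    if (acc > bestAcc) { bestAcc <- acc; best <- w }
  }
  list(weights = unname(best), accuracy = bestAcc)
}

# Pairwise-concordance AUC oracle with half credit for ties.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
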