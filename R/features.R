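#' @include sequences-io.R
NULL

#' Tokenize a sequence into overlapping k-mers
#'
#' Slides a width-`k` window across the sequence at stride 1, left to right,
#' yielding `L - k + 1` tokens (39 for the canonical 41-nt window with
#' k = 3).
#'
#' @param seq A single DNA string (character or [Biostrings::DNAString]).
#' @param k k-mer width, `1 <= k <= nchar(seq)`.
#' @return Character vector of k-mers.
#' @examples
#' tokenizeKmers("ATGCGA", 3)  # "ATG" "TGC" "GCG" "CGA"
#' @export
tokenizeKmers <- function(seq, k = 3L) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  k <- .assertCount(k, "k")
  L <- nchar(seq)
  if (k > L) stop("k (", k, ") exceeds sequence length (", L, ")",
                  call. = FALSE)
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Tokenize every record of a dataset
#'
#' One k-mer "sentence" per record, input order preserved.
#'
#' @param ds A [MethSeqSet-class].
#' @param k k-mer width.
#' @return List of character vectors (the corpus).
#' @export
buildCorpus <- function(ds, k = 3L) {
  stopifnot(methods::is(ds, "MethSeqSet"))
  lapply(as.character(ds@sequences), tokenizeKmers, k = k)
}

#' Word-embedding training parameters
#'
#' Defaults follow the standard small-corpus word2vec setup for k-mer
#' sentences: 100-dimensional vectors, context window 5, minimum corpus
#' count 5, five negative samples, 25 epochs, initial learning rate 0.025
#' with linear decay.
#'
#' @param vectorSize Embedding dimension.
#' @param window Context half-width in tokens.
#' @param minCount Minimum corpus count for vocabulary membership.
#' @param negative Number of negative samples per target.
#' @param epochs Training epochs.
#' @param alpha Initial learning rate.
#' @param seed Integer seed (training is single-threaded, so a fixed seed
#'   makes the vectors bitwise reproducible).
#' @return A validated parameter list of class `embeddingParams`.
#' @export
embeddingParams <- function(vectorSize = 100L, window = 5L, minCount = 5L,
                            negative = 5L, epochs = 25L, alpha = 0.025,
                            seed = 1L) {
  p <- list(vectorSize = .assertCount(vectorSize, "vectorSize"),
            window = .assertCount(window, "window"),
            minCount = .assertCount(minCount, "minCount"),
            negative = .assertCount(negative, "negative"),
            epochs = .assertCount(epochs, "epochs"),
            alpha = alpha, seed = as.integer(seed))
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("'alpha' must be positive", call. = FALSE)
  }
  class(p) <- "embeddingParams"
  p
}

#' Train a CBOW k-mer embedding
#'
#' Trains a continuous bag-of-words word2vec model with negative sampling on
#' a k-mer corpus. The vocabulary contains every token whose corpus count is
#' at least `minCount`, ordered by decreasing count (ties alphabetical);
#' rarer tokens are out of vocabulary and are skipped during training.
#'
#' @param corpus List of k-mer sentences from [buildCorpus()].
#' @param params An [embeddingParams()] list.
#' @return A [KmerEmbedding-class].
#' @export
trainEmbedding <- function(corpus, params = embeddingParams()) {
  stopifnot(inherits(params, "embeddingParams"))
  if (!length(corpus)) stop("corpus is empty", call. = FALSE)
  toks <- unlist(corpus, use.names = FALSE)
  if (!length(toks)) stop("corpus contains no tokens", call. = FALSE)
  tab <- table(toks)
  tab <- tab[tab >= params$minCount]
  if (!length(tab)) {
    stop("empty vocabulary: no token reaches minCount = ", params$minCount,
         call. = FALSE)
  }
  ord <- order(-as.integer(tab), names(tab))
  vocab <- names(tab)[ord]
  counts <- as.numeric(tab)[ord]
  sentences <- lapply(corpus, function(s) match(s, vocab) - 1L)
  sentences <- lapply(sentences, function(v) {
    v[is.na(v)] <- -1L
    as.integer(v)
  })
  vec <- .cbowTrain(sentences, length(vocab), counts,
                    params$vectorSize, params$window, params$negative,
                    params$epochs, params$alpha, params$seed)
  rownames(vec) <- vocab
  methods::new("KmerEmbedding", vectors = vec,
               k = nchar(vocab[1L]), params = unclass(params))
}

#' Look up the vector of one k-mer
#'
#' @param model A [KmerEmbedding-class].
#' @param token A k-mer string.
#' @return Numeric vector of length `vectorSize`; the all-zero vector for
#'   out-of-vocabulary tokens.
#' @export
embeddingVector <- function(model, token) {
  stopifnot(methods::is(model, "KmerEmbedding"))
  i <- match(token, rownames(model@vectors))
  if (is.na(i)) return(numeric(ncol(model@vectors)))
  model@vectors[i, ]
}

#' Embed a dataset as a feature tensor
#'
#' Stacks the embedding vectors of every record's tokens into an array of
#' shape `(n, L - k + 1, vectorSize)` — the `(39, 100)` input expected by
#' the convolutional base learners for 41-nt windows. Out-of-vocabulary
#' tokens map to the all-zero vector; their total count is reported in a
#' message and stored in `attr(x, "n_oov")`.
#'
#' @param ds A [MethSeqSet-class].
#' @param model A trained [KmerEmbedding-class] with matching `k`.
#' @param k k-mer width (must equal the model's).
#' @return Numeric 3-D array with record ids on the first dimension.
#' @export
embedSequences <- function(ds, model, k = 3L) {
  stopifnot(methods::is(ds, "MethSeqSet"), methods::is(model, "KmerEmbedding"))
  k <- .assertCount(k, "k")
  if (k != model@k) {
    stop("k (", k, ") does not match the embedding model (k = ", model@k,
         ")", call. = FALSE)
  }
  n <- length(ds)
  d <- ncol(model@vectors)
  if (n == 0L) {
    return(array(numeric(0), dim = c(0L, 0L, d)))
  }
  L <- seqLength(ds)
  Tlen <- L - k + 1L
  corpus <- buildCorpus(ds, k)
  tokmat <- matrix(match(unlist(corpus, use.names = FALSE),
                         rownames(model@vectors)),
                   nrow = n, ncol = Tlen, byrow = TRUE)
  nOOV <- sum(is.na(tokmat))
  if (nOOV > 0) {
    message(nOOV, " out-of-vocabulary token occurrence(s) mapped to the ",
            "zero vector")
  }
  Vext <- rbind(model@vectors, 0)
  tokmat[is.na(tokmat)] <- nrow(Vext)
  x <- array(Vext[as.vector(tokmat), , drop = FALSE], dim = c(n, Tlen, d))
  dimnames(x) <- list(names(ds), NULL, NULL)
  attr(x, "k") <- k
  attr(x, "n_oov") <- nOOV
  x
}

#' Serialize an embedding model to a plain-text table
#'
#' Writes `#`-prefixed parameter header lines followed by one
#' tab-separated `token vector...` row per vocabulary entry.
#'
#' @param model A [KmerEmbedding-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(model, path) {
  stopifnot(methods::is(model, "KmerEmbedding"))
  p <- model@params
  hdr <- sprintf("#%s=%s", names(p), vapply(p, format, ""))
  body <- paste(rownames(model@vectors),
                apply(model@vectors, 1L, function(v)
                  paste(format(v, digits = 17), collapse = "\t")),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an embedding model written by [writeEmbedding()]
#'
#' @param path Path to the table.
#' @return A [KmerEmbedding-class].
#' @export
readEmbedding <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  params <- stats::setNames(
    lapply(kv, function(x) {
      v <- utils::type.convert(x[2L], as.is = TRUE)
      if (is.numeric(v) && v == as.integer(v) && x[1L] != "alpha") {
        v <- as.integer(v)
      }
      v
    }),
    vapply(kv, `[`, "", 1L))
  body <- lines[!grepl("^#", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vocab <- vapply(parts, `[`, "", 1L)
  vec <- do.call(rbind, lapply(parts, function(x) as.numeric(x[-1L])))
  rownames(vec) <- vocab
  methods::new("KmerEmbedding", vectors = vec, k = nchar(vocab[1L]),
               params = params)
}

#' Export a corpus as one sentence per line
#'
#' @param corpus List of token vectors.
#' @param path Output path (space-separated tokens, plain text).
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, "", collapse = " "), path)
  invisible(path)
}
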