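#' @include MethSeqSet-methods.R
NULL

#' Read a FASTA file into a labeled dataset
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and attaches one
#' binary label to every record. Sequences are normalized to upper case.
#' Records containing characters outside A/C/G/T (including N) are rejected
#' with a warning; the number and ids of rejected records are stored in the
#' returned object's metadata (`metadata(x)$n_rejected`,
#' `metadata(x)$rejected_ids`).
#'
#' @param path Path to a FASTA file.
#' @param label Binary class applied to all records (1 = 4mC-positive,
#'   0 = non-4mC).
#' @param requireCenterC Enforce a central cytosine (odd lengths only).
#' @return A [MethSeqSet-class]; empty input yields an empty dataset.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTC", ">r2", "ttcag"), fa)
#' readFastaDataset(fa, label = 1)
#' @export
readFastaDataset <- function(path, label, requireCenterC = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  label <- .assertCount(label, "label", positive = FALSE)
  if (!label %in% c(0L, 1L)) stop("'label' must be 0 or 1", call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  # strip FASTA descriptions, keep the id token
  if (length(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- logical(length(seqs))
  if (length(seqs)) {
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    bad <- af[, "other"] > 0
  }
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (non-ACGT characters): ",
            paste(utils::head(names(seqs)[bad], 5L), collapse = ", "),
            call. = FALSE)
  }
  kept <- seqs[!bad]
  ds <- MethSeqSet(kept, labels = rep(label, length(kept)),
                   requireCenterC = requireCenterC)
  S4Vectors::metadata(ds) <- list(n_rejected = sum(bad),
                                  rejected_ids = names(seqs)[bad],
                                  source = path)
  ds
}

#' Write a dataset back to FASTA
#'
#' The label travels in the description line as `label=0` / `label=1`, so a
#' round trip through [readFastaLabeled()] restores the dataset.
#'
#' @param x A [MethSeqSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastaDataset <- function(x, path) {
  stopifnot(methods::is(x, "MethSeqSet"))
  seqs <- x@sequences
  names(seqs) <- paste0(names(seqs), " label=", x@labels)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a FASTA file whose descriptions carry `label=` tags
#'
#' Companion reader for files written by [writeFastaDataset()].
#'
#' @param path Path to the FASTA file.
#' @param requireCenterC Enforce a central cytosine.
#' @return A [MethSeqSet-class].
#' @export
readFastaLabeled <- function(path, requireCenterC = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  lab <- sub("^.*label=([01]).*$", "\\1", names(seqs))
  if (length(seqs) && any(lab == names(seqs))) {
    stop("missing 'label=' tag in FASTA description(s)", call. = FALSE)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  MethSeqSet(seqs, labels = as.integer(lab), requireCenterC = requireCenterC)
}

#' Attach labels from a two-column table
#'
#' Alternative labeling route: a headerless two-column TSV (id, label).
#'
#' @param ds A [MethSeqSet-class] (labels are replaced).
#' @param path Path to the TSV.
#' @return The relabeled dataset; ids missing from the table are an error.
#' @export
applyLabelTable <- function(ds, path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  idx <- match(names(ds), tab$id)
  if (anyNA(idx)) {
    stop("label table is missing id(s): ",
         paste(utils::head(names(ds)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  methods::initialize(ds, labels = tab$label[idx])
}

#' Greedy identity-based redundancy filter
#'
#' Single deterministic pass in input order: a record is kept iff its
#' positional identity (fraction of matching positions over the common
#' length) with every previously kept record of the *same* label is below
#' `threshold`. This is a desk-scale stand-in for CD-HIT-style clustering,
#' valid because all records share one length; it is applied per class so
#' near-identical sequences with opposite labels are both retained.
#'
#' @param ds A [MethSeqSet-class] (equal-length records).
#' @param threshold Identity fraction in (0, 1]; the conventional redundancy
#'   cutoff in this literature is 0.8.
#' @param perClass Compare only within the same label (default) or across
#'   the whole set.
#' @return The filtered [MethSeqSet-class], input order preserved.
#' @examples
#' ds <- MethSeqSet(c("ACGTA", "ACGTA", "TTTTT"), labels = c(1, 1, 1))
#' length(redundancyFilter(ds, 0.8))  # exact duplicate removed -> 2
#' @export
redundancyFilter <- function(ds, threshold = 0.8, perClass = TRUE) {
  stopifnot(methods::is(ds, "MethSeqSet"))
  .assertFraction(threshold, "threshold", open = FALSE)
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  n <- length(ds)
  if (n <= 1L) return(ds)
  mat <- as.matrix(ds@sequences)          # n x L character matrix
  L <- ncol(mat)
  keep <- logical(n)
  groups <- if (perClass) ds@labels else rep(0L, n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    keptRows <- integer(0)
    for (i in idx) {
      if (length(keptRows)) {
        ident <- rowMeans(mat[keptRows, , drop = FALSE] ==
                            matrix(mat[i, ], length(keptRows), L,
                                   byrow = TRUE))
        if (any(ident >= threshold)) next
      }
      keep[i] <- TRUE
      keptRows <- c(keptRows, i)
    }
  }
  ds[which(keep)]
}

#' Balance classes by random undersampling
#'
#' Randomly undersamples the majority class, without replacement, down to
#' the minority-class size; the minority class is untouched. Record order is
#' preserved and all randomness flows from `seed`.
#'
#' @param ds A [MethSeqSet-class] with both classes non-empty.
#' @param seed Integer seed.
#' @return A balanced [MethSeqSet-class] with `|S+| == |S-|`.
#' @export
balanceDataset <- function(ds, seed = 1L) {
  stopifnot(methods::is(ds, "MethSeqSet"))
  nPos <- sum(ds@labels == 1L)
  nNeg <- sum(ds@labels == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be non-empty to balance", call. = FALSE)
  }
  if (nPos == nNeg) return(ds)
  majLabel <- if (nPos > nNeg) 1L else 0L
  target <- min(nPos, nNeg)
  majIdx <- which(ds@labels == majLabel)
  selMaj <- withr::with_seed(.deriveSeed(seed, 1L),
                             sample(majIdx, target))
  ds[sort(c(which(ds@labels != majLabel), selMaj))]
}

#' Stratified train/test split
#'
#' Per class, the test count is round-half-up of
#' `(1 - trainFraction) * n_class` (so 388 records per class at an 80:20
#' split yield 78 test records per class); selection is random within class
#' and seeded. Train and test are disjoint and their union is the input.
#'
#' @param ds A [MethSeqSet-class].
#' @param trainFraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed.
#' @return `list(train = , test = )` of [MethSeqSet-class] objects.
#' @export
stratifiedSplit <- function(ds, trainFraction = 0.8, seed = 1L) {
  stopifnot(methods::is(ds, "MethSeqSet"))
  .assertFraction(trainFraction, "trainFraction")
  testIdx <- integer(0)
  withr::with_seed(.deriveSeed(seed, 2L), {
    for (lab in c(0L, 1L)) {
      idx <- which(ds@labels == lab)
      if (!length(idx)) next
      nTest <- floor((1 - trainFraction) * length(idx) + 0.5)
      if (nTest < 1L) {
        stop("class ", lab, " is too small: its test count would be 0",
             call. = FALSE)
      }
      if (nTest >= length(idx)) {
        stop("degenerate split: class ", lab,
             " would have no training records", call. = FALSE)
      }
      testIdx <- c(testIdx, sample(idx, nTest))
    }
  })
  testIdx <- sort(testIdx)
  list(train = ds[setdiff(seq_len(length(ds)), testIdx)],
       test = ds[testIdx])
}
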