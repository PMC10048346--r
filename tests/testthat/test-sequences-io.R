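test_that("FASTA reading parses, labels, uppercases and preserves order", {
  path <- writeFastaFixture(c("acgtC", "TTCAG"), ids = c("r1", "r2"))
  ds <- readFastaDataset(path, label = 1)
  expect_s4_class(ds, "MethSeqSet")
  expect_identical(names(ds), c("r1", "r2"))
  expect_identical(as.character(sequences(ds)),
                   c(r1 = "ACGTC", r2 = "TTCAG"))
  expect_identical(labels(ds), c(1L, 1L))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(readFastaDataset(empty, label = 0), 0L)

  expect_error(readFastaDataset(tempfile(), 1), "not found")
})

test_that("records with non-ACGT characters are rejected and counted", {
  path <- writeFastaFixture(c("ACGTN", "ACGTA", "ACRTA"),
                            ids = c("bad1", "ok", "bad2"))
  expect_warning(ds <- readFastaDataset(path, label = 0), "2 record")
  expect_identical(names(ds), "ok")
  expect_identical(S4Vectors::metadata(ds)$n_rejected, 2L)
  expect_setequal(S4Vectors::metadata(ds)$rejected_ids, c("bad1", "bad2"))
})

test_that("datasets round-trip through label-tagged FASTA", {
  ds <- generateDataset(syntheticSpec(nPos = 4, nNeg = 3, seed = 2))
  path <- tempfile(fileext = ".fa")
  writeFastaDataset(ds, path)
  back <- readFastaLabeled(path)
  expect_identical(as.character(sequences(back)),
                   as.character(sequences(ds)))
  expect_identical(labels(back), labels(ds))
})

test_that("label tables relabel by id and catch missing ids", {
  ds <- MethSeqSet(c("ACGTA", "TTTTT"), labels = c(0, 0),
                   ids = c("a", "b"))
  tab <- tempfile()
  writeLines(c("b\t1", "a\t0"), tab)
  expect_identical(labels(applyLabelTable(ds, tab)), c(0L, 1L))
  writeLines("a\t0", tab)
  expect_error(applyLabelTable(ds, tab), "missing id")
})

test_that("dataset validity enforces alphabet, equal length and center C", {
  expect_error(MethSeqSet(c("ACGT", "ACGTA"), labels = c(0, 1)),
               "share one length")
  expect_error(MethSeqSet("ACNGA", labels = 1), "A/C/G/T")
  expect_error(MethSeqSet("ACGTA", labels = 2), "0 or 1")
  expect_error(MethSeqSet("ACTTA", labels = 1, requireCenterC = TRUE),
               "centered-cytosine")
  expect_silent(MethSeqSet("ACCTA", labels = 1, requireCenterC = TRUE))
})

test_that("redundancy filter drops duplicates but keeps sub-threshold pairs", {
  base <- randomDna(41)
  # flip 9 of 41 positions: identity 32/41 ~ 0.78 < 0.8
  chars <- strsplit(base, "")[[1]]
  flip <- c(1, 5, 9, 13, 17, 21, 25, 29, 33)
  chars[flip] <- chartr("ACGT", "TGCA", chars[flip])
  variant <- paste(chars, collapse = "")
  ds <- MethSeqSet(c(base, base, variant), labels = c(1, 1, 1))
  kept <- redundancyFilter(ds, 0.8)
  expect_length(kept, 2L)
  expect_identical(as.character(sequences(kept))[[2]], variant)
})

test_that("redundancy filter is per class, order-stable and idempotent", {
  set.seed(41)
  # two-letter alphabet so that random pairs often exceed a 0.6 cutoff
  seqs <- replicate(40, randomDna(20, c("A", "C")))
  labs <- rep(c(0L, 1L), 20)
  ds <- MethSeqSet(seqs, labels = labs)
  out <- redundancyFilter(ds, 0.6)
  oracle <- greedyFilterOracle(seqs, labs, 0.6)
  expect_identical(names(out), paste0("seq", which(oracle)))
  twice <- redundancyFilter(out, 0.6)
  expect_identical(as.character(sequences(twice)),
                   as.character(sequences(out)))
  # same-sequence, opposite-label records survive a per-class filter
  ds2 <- MethSeqSet(c("ACGTA", "ACGTA"), labels = c(0, 1))
  expect_length(redundancyFilter(ds2, 0.8), 2L)
  # threshold 1.0 keeps every distinct record
  expect_length(redundancyFilter(ds, 1), length(ds))
})

test_that("balancing undersamples the majority class to equality", {
  set.seed(7)
  ds <- MethSeqSet(replicate(1388, randomDna(11)),
                   labels = rep(c(1L, 0L), c(388L, 1000L)))
  bal <- balanceDataset(ds, seed = 3)
  expect_identical(sum(labels(bal) == 1L), 388L)
  expect_identical(sum(labels(bal) == 0L), 388L)
  # minority class untouched, order preserved
  expect_identical(names(bal)[labels(bal) == 1L], names(ds)[1:388])
  expect_false(is.unsorted(match(names(bal), names(ds))))
  # determinism and seed sensitivity
  expect_identical(names(balanceDataset(ds, seed = 3)), names(bal))
  expect_false(identical(names(balanceDataset(ds, seed = 4)), names(bal)))
  # already balanced input is returned unchanged
  balTwice <- balanceDataset(bal, seed = 99)
  expect_identical(names(balTwice), names(bal))
  expect_error(balanceDataset(ds[1:388], seed = 1), "both classes")
})

test_that("stratified split uses round-half-up per class and conserves", {
  ds <- generateDataset(syntheticSpec(nPos = 388, nNeg = 388, seed = 5))
  sp <- stratifiedSplit(ds, 0.8, seed = 5)
  expect_identical(sum(labels(sp$test) == 1L), 78L)   # 0.2 * 388 = 77.6
  expect_identical(sum(labels(sp$test) == 0L), 78L)
  expect_identical(length(sp$train) + length(sp$test), length(ds))
  expect_length(intersect(names(sp$train), names(sp$test)), 0L)
  expect_setequal(c(names(sp$train), names(sp$test)), names(ds))

  ds2 <- generateDataset(syntheticSpec(nPos = 1154, nNeg = 1154, seed = 5))
  sp2 <- stratifiedSplit(ds2, 0.8, seed = 1)
  expect_identical(sum(labels(sp2$test) == 1L), 231L)
  expect_identical(sum(labels(sp2$test) == 0L), 231L)

  tiny <- generateDataset(syntheticSpec(nPos = 2, nNeg = 2, seed = 1))
  expect_error(stratifiedSplit(tiny, 0.9, seed = 1), "test count would be 0")
  expect_error(stratifiedSplit(tiny, 0.1, seed = 1), "degenerate")
})
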