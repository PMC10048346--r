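test_that("weighted averaging normalizes by the weight sum", {
  expect_equal(weightedAveragePredict(cbind(0.8, 0.2, 0.6),
                                      c(0.3, 0.5, 0.2)), 0.46)
  P <- cbind(c(0.1, 0.9), c(0.5, 0.5), c(0.8, 0.3))
  expect_equal(weightedAveragePredict(P, c(1, 0, 0)), P[, 1])
  expect_equal(weightedAveragePredict(P, c(1, 1, 1)), rowMeans(P))
  # scale invariance
  expect_equal(weightedAveragePredict(P, c(0.2, 0.3, 0.1)),
               weightedAveragePredict(P, 10 * c(0.2, 0.3, 0.1)))
  expect_error(weightedAveragePredict(P, c(0, 0, 0)), "all be zero")
  expect_error(weightedAveragePredict(P, c(1, 1)), "one weight per")
  expect_error(weightedAveragePredict(list(c(0.1, 0.2), 0.3), c(1, 1)),
               "different record counts")
  expect_error(weightedAveragePredict(cbind(1.2), 1), "\\[0, 1\\]")
})

test_that("grid search matches brute-force enumeration and breaks ties low", {
  set.seed(99)
  for (trial in 1:20) {
    m <- sample(1:3, 1)
    n <- sample(5:12, 1)
    P <- matrix(runif(n * m), n, m)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    step <- sample(c(0.5, 0.25, 0.1), 1)
    got <- gridSearchWeights(P, y, gridStep = step)
    want <- gridSearchOracle(P, y, step)
    expect_equal(got$weights, want$weights)
    expect_equal(got$accuracy, want$accuracy)
  }
  # a perfect member dominates
  y <- c(1, 1, 0, 0)
  P <- cbind(c(0.9, 0.8, 0.1, 0.2), runif(4), runif(4))
  got <- gridSearchWeights(P, y)
  expect_equal(got$accuracy, 1)
  # identical members: every tuple ties, the lexicographically smallest wins
  P3 <- matrix(rep(c(0.9, 0.2, 0.7, 0.4), 3), 4, 3)
  expect_equal(gridSearchWeights(P3, c(1, 0, 1, 0))$weights, c(0, 0, 0.1))
  expect_error(gridSearchWeights(matrix(0, 0, 2), integer(0)),
               "empty test set")
})

test_that("classification partitions records and balances the books", {
  p <- c(0.9, 0.4, 0.6, 0.2, 0.5)
  y <- c(1, 1, 0, 0, 1)
  out <- classifyAndPartition(p, y)
  expect_identical(out$counts@TP, 2L)  # 0.9, 0.5 (>= threshold counts as 1)
  expect_identical(out$counts@TN, 1L)  # 0.2
  expect_identical(out$counts@FP, 1L)  # 0.6 against label 0
  expect_identical(out$counts@FN, 1L)  # 0.4 against label 1
  expect_identical(sort(c(out$correct, out$incorrect)), 1:5)
  all_right <- classifyAndPartition(c(0.9, 0.1), c(1, 0))
  expect_length(all_right$incorrect, 0L)
})

test_that("total accuracy aggregates per-layer correct counts over the initial test", {
  expect_equal(totalAccuracy(c(110, 39), 156), 149 / 156)
  expect_equal(totalAccuracy(c(384, 197, 87), 708), 668 / 708)
  expect_equal(totalAccuracy(50, 50), 1)
  expect_error(totalAccuracy(c(100, 100), 156), "internal-consistency")
  df <- data.frame(TP = c(87, 32), TN = c(23, 7))
  expect_equal(totalAccuracy(df, 156), 149 / 156)
})

test_that("the cascade obeys its ledger invariants and conservation law", {
  ds <- generateDataset(strongSpec(120, 120, seed = 17))
  sp <- stratifiedSplit(ds, 0.8, seed = 17)
  res <- runMLDS(sp$train, sp$test, learners = referenceTrio(17),
                 embedding = fastEmbedding(ds, seed = 17), seed = 17)
  led <- layerLedger(res)
  expect_true(all(led$TP + led$TN + led$FP + led$FN == led$test_size))
  if (nrow(led) > 1) {
    expect_identical(led$train_size[-1],
                     head(led$train_size + led$TP + led$TN, -1))
    expect_identical(led$test_size[-1], head(led$FP + led$FN, -1))
  }
  resolved <- sum(led$TP + led$TN)
  expect_identical(resolved + sum(is.na(res@assignments$layer)),
                   res@initialTestSize)
  expect_true(all(diff(led$cumulative_accuracy) >= 0))
  expect_equal(totalAccuracy(res), res@totalAccuracy)
  # per-record assignments agree with the ledger
  expect_identical(sum(!is.na(res@assignments$layer)), resolved)
  expect_true(all(res@assignments$predicted[!is.na(res@assignments$layer)] ==
                  res@assignments$label[!is.na(res@assignments$layer)]))
})

test_that("the cascade run is reproducible and validates its inputs", {
  ds <- generateDataset(strongSpec(60, 60, seed = 23))
  sp <- stratifiedSplit(ds, 0.8, seed = 23)
  emb <- fastEmbedding(ds, seed = 23)
  r1 <- runMLDS(sp$train, sp$test, learners = referenceTrio(23),
                embedding = emb, seed = 23)
  r2 <- runMLDS(sp$train, sp$test, learners = referenceTrio(23),
                embedding = emb, seed = 23)
  expect_identical(layerLedger(r1), layerLedger(r2))
  expect_error(runMLDS(sp$train, sp$train[1:5], learners = referenceTrio(23),
                       embedding = emb), "not disjoint")
  expect_error(runMLDS(sp$train, sp$test[integer(0)],
                       learners = referenceTrio(23), embedding = emb),
               "test set is empty")
})

test_that("a stalled layer (no correct calls) terminates the loop", {
  # motifless data with a single weak learner often stalls; force it with
  # maxLayers as backstop and check the stopping bookkeeping either way
  ds <- generateDataset(syntheticSpec(nPos = 40, nNeg = 40,
                                      motifStrength = 0, seed = 31))
  sp <- stratifiedSplit(ds, 0.8, seed = 31)
  res <- runMLDS(sp$train, sp$test, learners = referenceTrio(31),
                 embedding = fastEmbedding(ds, seed = 31), seed = 31,
                 maxLayers = 10)
  led <- layerLedger(res)
  lastCorrect <- led$TP[nrow(led)] + led$TN[nrow(led)]
  if (lastCorrect == 0) {
    # loop stopped exactly at the stall; unresolved records count as errors
    expect_identical(sum(led$TP + led$TN) + led$FP[nrow(led)] +
                       led$FN[nrow(led)], res@initialTestSize)
  }
  expect_lte(nrow(led), 10L)
  expect_equal(res@totalAccuracy, sum(led$TP + led$TN) / res@initialTestSize)
})

test_that("AE and honest modes run and produce valid ledgers", {
  ds <- generateDataset(strongSpec(60, 60, seed = 37))
  sp <- stratifiedSplit(ds, 0.8, seed = 37)
  emb <- fastEmbedding(ds, seed = 37)
  ae <- runMLDS(sp$train, sp$test, learners = referenceTrio(37),
                embedding = emb, ensemble = "AE", seed = 37)
  ledAE <- layerLedger(ae)
  expect_true(all(ledAE$w1 == 1 & ledAE$w2 == 1 & ledAE$w3 == 1))
  hon <- runMLDS(sp$train, sp$test, learners = referenceTrio(37),
                 embedding = emb, mode = "honest", seed = 37)
  expect_identical(hon@mode, "honest")
  expect_true(all(layerLedger(hon)$TP + layerLedger(hon)$TN +
                  layerLedger(hon)$FP + layerLedger(hon)$FN ==
                  layerLedger(hon)$test_size))
})

test_that("ledgers serialize to readable TSV", {
  ds <- generateDataset(strongSpec(40, 40, seed = 41))
  sp <- stratifiedSplit(ds, 0.8, seed = 41)
  res <- runMLDS(sp$train, sp$test, learners = referenceTrio(41),
                 embedding = fastEmbedding(ds, seed = 41), seed = 41)
  path <- tempfile(fileext = ".tsv")
  writeLedger(res, path)
  back <- read.delim(path)
  expect_identical(nrow(back), nrow(layerLedger(res)))
  expect_identical(back$TP, layerLedger(res)$TP)
  expect_match(back$weights[1], "^[0-9.]+(,[0-9.]+)*$")
})
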