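# Published per-species test-set tallies for eight 4mC benchmark species:
# correctly called positives/negatives out of the per-class test totals,
# and the metric table computed from them (percent, two decimals as
# printed; truncate-vs-round ambiguity means agreement to within 0.01).
speciesCounts <- list(
  C_elegans      = list(pos = c(226, 231), neg = c(222, 231),
                        row = c(acc = 96.96, precision = 96.17,
                                recall = 97.83, fpr = 3.89, tnr = 96.10,
                                fnr = 2.16)),
  D_melanogaster = list(pos = c(337, 354), neg = c(331, 354),
                        row = c(acc = 94.35, precision = 93.61,
                                recall = 95.19, fpr = 6.49, tnr = 93.50,
                                fnr = 4.80)),
  A_thaliana     = list(pos = c(379, 396), neg = c(352, 396),
                        row = c(acc = 92.29, precision = 89.59,
                                recall = 95.70, fpr = 11.11, tnr = 88.88,
                                fnr = 4.29)),
  E_coli         = list(pos = c(75, 78), neg = c(74, 78),
                        row = c(acc = 95.51, precision = 94.93,
                                recall = 96.15, fpr = 5.12, tnr = 94.87,
                                fnr = 3.84)),
  G_subterraneus = list(pos = c(177, 182), neg = c(179, 181),
                        row = c(acc = 98.07, precision = 98.88,
                                recall = 97.25, fpr = 1.10, tnr = 98.89,
                                fnr = 2.74)),
  G_pickeringi   = list(pos = c(112, 114), neg = c(108, 114),
                        row = c(acc = 96.49, precision = 94.91,
                                recall = 98.24, fpr = 5.26, tnr = 94.73,
                                fnr = 1.75)),
  F_vesca        = list(pos = c(852, 865), neg = c(799, 864),
                        row = c(acc = 95.48, precision = 92.91,
                                recall = 98.49, fpr = 7.52, tnr = 92.47,
                                fnr = 1.50)),
  R_chinensis    = list(pos = c(476, 485), neg = c(461, 484),
                        row = c(acc = 96.69, precision = 95.39,
                                recall = 98.14, fpr = 4.75, tnr = 95.24,
                                fnr = 1.85)))

countsFromTallies <- function(sp) {
  confusionCounts(TP = sp$pos[1], FN = sp$pos[2] - sp$pos[1],
                  TN = sp$neg[1], FP = sp$neg[2] - sp$neg[1])
}

test_that("the metric suite reproduces the published per-species table", {
  for (nm in names(speciesCounts)) {
    sp <- speciesCounts[[nm]]
    m <- 100 * computeMetrics(countsFromTallies(sp))
    expect_lt(abs(m[["accuracy"]] - sp$row[["acc"]]), 0.01, label = nm)
    expect_lt(abs(m[["precision"]] - sp$row[["precision"]]), 0.01,
              label = nm)
    expect_lt(abs(m[["recall"]] - sp$row[["recall"]]), 0.01, label = nm)
    expect_lt(abs(m[["fpr"]] - sp$row[["fpr"]]), 0.01, label = nm)
    expect_lt(abs(m[["tnr"]] - sp$row[["tnr"]]), 0.01, label = nm)
    expect_lt(abs(m[["fnr"]] - sp$row[["fnr"]]), 0.01, label = nm)
  }
})

test_that("perfect and degenerate classifiers are handled correctly", {
  perfect <- computeMetrics(confusionCounts(TP = 10, TN = 12, FP = 0,
                                            FN = 0))
  expect_equal(unname(perfect[c("accuracy", "precision", "recall", "tnr")]),
               rep(1, 4))
  expect_equal(unname(perfect[c("fpr", "fnr")]), c(0, 0))
  w <- capture_warnings(m <- computeMetrics(confusionCounts(TP = 0, TN = 5,
                                                            FP = 0, FN = 3)))
  expect_match(w, "precision is undefined", all = FALSE)
  expect_true(is.na(m[["precision"]]))
  expect_false(is.na(m[["recall"]]))
  w2 <- capture_warnings(m2 <- computeMetrics(confusionCounts(0, 5, 0, 0)))
  expect_match(w2, "recall is undefined", all = FALSE)
  expect_true(is.na(m2[["fnr"]]))
})

test_that("complement identities hold exactly for arbitrary counts", {
  set.seed(12)
  for (i in 1:25) {
    cc <- confusionCounts(TP = sample(1:500, 1), TN = sample(1:500, 1),
                          FP = sample(1:500, 1), FN = sample(1:500, 1))
    m <- computeMetrics(cc)
    expect_equal(m[["recall"]] + m[["fnr"]], 1)
    expect_equal(m[["tnr"]] + m[["fpr"]], 1)
    expect_equal(m[["accuracy"]],
                 (cc@TP + cc@TN) / (cc@TP + cc@TN + cc@FP + cc@FN))
  }
})

test_that("trapezoidal AUC equals the pairwise-concordance statistic", {
  expect_equal(rocCurveAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocCurveAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(rocCurveAuc(s, y)$auc, aucOracle(s, y))
  }
  expect_error(rocCurveAuc(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("label swap mirrors the AUC and pROC agrees on the curve", {
  set.seed(9)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- round(runif(40), 2)
  a <- rocCurveAuc(s, y)$auc
  expect_equal(rocCurveAuc(s, 1 - y)$auc, 1 - a)
  ref <- suppressMessages(pROC::auc(pROC::roc(y, s, direction = "<")))
  expect_equal(a, as.numeric(ref))
})

test_that("ROC points trace monotone rates from (0,0) to (1,1)", {
  set.seed(4)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  roc <- rocCurveAuc(runif(30), y)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("balanced accuracy is the TPR/TNR midpoint", {
  cc <- confusionCounts(TP = 75, FN = 3, TN = 74, FP = 4)
  expect_equal(balancedAccuracy(cc), (75 / 78 + 74 / 78) / 2)
})
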