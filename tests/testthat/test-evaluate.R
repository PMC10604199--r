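test_that("confusion counts match a loop-based recount", {
  expect_equal(unclass(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))[1:4],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  cc <- confusion(c(1, 1), c(1, 0))
  expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), c(1, 1, 0, 0))
  expect_error(confusion(c(1, 0), c(1)), "length")

  set.seed(10)
  pred <- rbinom(100, 1, 0.5); lab <- rbinom(100, 1, 0.5)
  got <- confusion(pred, lab)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:100) {                      # independent brute-force recount
    if (pred[i] == 1 && lab[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && lab[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && lab[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && lab[i] == 1) fn <- fn + 1
  }
  expect_equal(c(got$TP, got$TN, got$FP, got$FN), c(tp, tn, fp, fn))
})

test_that("metrics match hand arithmetic on the worked confusion table", {
  m <- metrics_from_counts(confusion(rep(c(1, 0), c(11, 9)),
                                     c(rep(1, 8), rep(0, 3), rep(0, 7), rep(1, 2))))
  # TP=8, FP=3, TN=7, FN=2
  expect_equal(m$accuracy, 0.75, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.8, tolerance = 1e-12)
  expect_equal(m$specificity_as_printed, 8 / 11, tolerance = 1e-12)
  expect_equal(m$f1_as_printed, 2 * 0.8 * (8 / 11) / (0.8 + 8 / 11),
               tolerance = 1e-12)
  expect_equal(m$specificity_standard, 0.7, tolerance = 1e-12)

  perfect <- metrics_from_counts(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_true(all(unlist(perfect) == 1))
})

test_that("as-printed F1 equals standard F1 identically and oracles agree", {
  # the as-printed specificity is algebraically precision, which forces the
  # two F1 variants to coincide; checked exactly on random tables together
  # with a brute-force metric oracle
  set.seed(77)
  for (i in 1:1000) {
    cts <- structure(as.list(rmultinom(1, sample(4:200, 1), rep(0.25, 4))[, 1]),
                     names = c("TP", "TN", "FP", "FN"), class = "confusion_counts")
    m <- metrics_from_counts(cts)
    with(cts, {
      total <- TP + TN + FP + FN
      expect_identical(m$accuracy, (TP + TN) / total)
      if (TP + FN > 0) expect_identical(m$sensitivity, TP / (TP + FN))
      else expect_true(is.na(m$sensitivity))
      if (TP + FP > 0) expect_identical(m$specificity_as_printed, TP / (TP + FP))
      else expect_true(is.na(m$specificity_as_printed))
      if (TN + FP > 0) expect_identical(m$specificity_standard, TN / (TN + FP))
    })
    expect_identical(m$f1_as_printed, m$f1_standard)
  }
})

test_that("zero-denominator metrics are undefined, not clamped", {
  m <- metrics_from_counts(confusion(c(0, 0), c(0, 0)))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$specificity_as_printed))
  expect_true(is.na(m$f1_as_printed))
  expect_equal(m$accuracy, 1)
})

test_that("rank AUC matches the all-pairs oracle, ties counted half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  auc_brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # coarse rounding forces ties
    expect_equal(roc_auc(s, y), auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-10)
})

test_that("stratified folds are balanced, disjoint, exhaustive and seeded", {
  labs <- rep(c(1, 0), each = 10)
  f <- make_folds(labs, k = 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k), 4)
    expect_equal(sum(f == k & labs == 1), 2)   # 2 EP + 2 HC per fold
  }
  expect_identical(f, make_folds(labs, k = 5, seed = 3))
  expect_false(identical(f, make_folds(labs, k = 5, seed = 4)))
  expect_error(make_folds(c(1, 1, 1, 0), k = 5), "at least k")
})
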