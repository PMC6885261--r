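# Metric suite: stratified folds, confusion-matrix identities, kappa, AUC.

test_that("stratified folds balance classes exactly when divisible", {
  labels <- factor(rep(c("Normal", "Myopathy", "Neuropathy"), each = 800),
                   levels = c("Normal", "Myopathy", "Neuropathy"))
  folds <- stratified_fold_indices(labels, 10, seed = 1L)
  expect_length(folds, 10L)
  expect_identical(sort(unlist(folds)), seq_along(labels))
  for (f in folds) {
    expect_identical(as.integer(table(labels[f])), c(80L, 80L, 80L))
  }
  folds2 <- stratified_fold_indices(labels, 10, seed = 1L)
  expect_identical(folds, folds2)
})

test_that("leave-one-out folds are singletons and rare classes error", {
  labels <- factor(rep(c("A", "B"), 5))
  folds <- stratified_fold_indices(labels, 10, seed = 2L)
  expect_true(all(lengths(folds) == 1L))
  labels2 <- factor(c(rep("A", 20), rep("B", 5)))
  expect_error(stratified_fold_indices(labels2, 10, seed = 1L),
               "rarer than k")
})

test_that("per-fold class counts deviate from proportionality by at most 1", {
  set.seed(81)
  labels <- factor(sample(c("A", "B", "C"), 203, TRUE, c(.5, .3, .2)))
  folds <- stratified_fold_indices(labels, 7, seed = 3L)
  for (cl in levels(labels)) {
    per_fold <- vapply(folds, function(f) sum(labels[f] == cl), integer(1))
    expect_lte(diff(range(per_fold)), 1L)
  }
})

test_that("confusion matrices count one-vs-rest cells correctly", {
  cm <- confusion(factor(c("A", "A", "A", "B"), levels = c("A", "B")),
                  c("A", "B", "A", "B"))
  expect_identical(cm["A", "A"], 2L)  # TP for A
  expect_identical(cm["A", "B"], 1L)  # FN for A
  expect_identical(cm["B", "A"], 0L)  # FP for A
  expect_identical(cm["B", "B"], 1L)  # TN for A
  perfect <- confusion(factor(c("A", "B", "B")), c("A", "B", "B"))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  allA <- confusion(factor(c("A", "B", "B")), c("A", "A", "A"))
  expect_identical(sum(allA[, "B"]), 0L)
  expect_error(confusion(factor(c("A", "B")), c("A", "C")), "unknown class")
})

test_that("precision/recall/F match the closed-form worked example", {
  # TP = 40, FN = 10, FP = 5 on a 2-class matrix
  cm <- matrix(c(40L, 5L, 10L, 45L), 2,
               dimnames = list(true = c("P", "N"), predicted = c("P", "N")))
  prf <- precision_recall_f(cm, "P")
  expect_equal(unname(prf["recall"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(prf["precision"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(prf["F"]), 16 / 19, tolerance = 1e-12)

  cm2 <- matrix(c(8L, 2L, 2L, 8L), 2,
                dimnames = list(c("P", "N"), c("P", "N")))
  expect_equal(unname(precision_recall_f(cm2, 1)), c(0.8, 0.8, 0.8))

  cm3 <- matrix(c(0L, 0L, 5L, 10L), 2,
                dimnames = list(c("P", "N"), c("P", "N")))
  expect_warning(prf3 <- precision_recall_f(cm3, 1), "undefined")
  expect_equal(unname(prf3), c(0, 0, 0))
})

test_that("accuracy follows the trace formula", {
  cm <- matrix(c(45L, 5L, 5L, 45L), 2)
  expect_equal(accuracy(cm), 90)
  expect_equal(accuracy(diag(c(10L, 20L, 30L))), 100)
  set.seed(82)
  truth <- sample(c("A", "B", "C"), 1e5, TRUE)
  pred <- sample(c("A", "B", "C"), 1e5, TRUE)
  cm_mc <- confusion(factor(truth), pred)
  expect_lt(abs(accuracy(cm_mc) - 100 / 3), 0.5)
  expect_error(accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("kappa matches the worked example and its fixed points", {
  cm <- matrix(c(40L, 5L, 10L, 45L), 2)
  k <- kappa_statistic(cm)
  expect_equal(as.numeric(k), 0.7, tolerance = 1e-12)
  expect_equal(attr(k, "P0"), 0.85)
  expect_equal(attr(k, "Pe"), 0.5)
  expect_equal(as.numeric(kappa_statistic(diag(c(7L, 3L, 5L)))), 1)
  set.seed(83)
  truth <- sample(c("A", "B", "C"), 1e5, TRUE, c(.5, .3, .2))
  pred <- sample(c("A", "B", "C"), 1e5, TRUE, c(.2, .5, .3))
  expect_lt(abs(as.numeric(kappa_statistic(confusion(factor(truth), pred)))),
            0.02)
  expect_warning(k0 <- kappa_statistic(matrix(c(5L, 0L, 0L, 0L), 2)),
                 "degenerate")
  expect_identical(as.numeric(k0), 0)
})

test_that("kappa is invariant under class permutation, 1 only on diagonal", {
  set.seed(84)
  cm <- matrix(sample.int(50, 9), 3)
  for (perm in list(c(2, 1, 3), c(3, 1, 2))) {
    expect_equal(as.numeric(kappa_statistic(cm[perm, perm])),
                 as.numeric(kappa_statistic(cm)))
  }
  off <- diag(c(5L, 5L, 5L))
  off[1, 2] <- 1L
  expect_lt(as.numeric(kappa_statistic(off)), 1)
})

test_that("AUC matches brute-force pair counting and its invariances", {
  # binary case via the two-column score matrix
  sc <- cbind(c(0.9, 0.8, 0.4, 0.3), 1 - c(0.9, 0.8, 0.4, 0.3))
  y <- factor(c("P", "P", "N", "N"), levels = c("P", "N"))
  expect_equal(auc_ovr(sc, y), 1)
  y2 <- factor(c("P", "N", "P", "N"), levels = c("P", "N"))
  expect_equal(auc_ovr(sc, y2), 0.75)
  # monotone transform of scores leaves ranks, hence AUC, unchanged
  expect_equal(auc_ovr(exp(3 * sc), y2), 0.75)
  # chance level under independence
  set.seed(85)
  n <- 1e4
  sc3 <- matrix(runif(3 * n), n)
  sc3 <- sc3 / rowSums(sc3)
  y3 <- factor(sample(c("A", "B", "C"), n, TRUE))
  expect_lt(abs(auc_ovr(sc3, y3) - 0.5), 0.02)
  expect_error(auc_ovr(sc, factor(c("P", "P", "P", "P"),
                                  levels = c("P", "N"))),
               "at least two classes")
})

test_that("weighted-average recall equals accuracy/100 on random matrices", {
  set.seed(86)
  for (i in 1:20) {
    cm <- matrix(sample.int(30, 9, TRUE), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    rep_ <- suppressWarnings(metrics_report(cm))
    expect_equal(unname(rep_$weighted["recall"]), rep_$accuracy / 100,
                 tolerance = 1e-12)
  }
})

test_that("the metrics report carries all components", {
  cm <- confusion(factor(c("A", "A", "B", "B")), c("A", "B", "B", "B"))
  sc <- cbind(c(.9, .4, .2, .1), c(.1, .6, .8, .9))
  rep_ <- metrics_report(cm, sc, factor(c("A", "A", "B", "B")),
                         fold_accuracies = c(75, 75))
  expect_s3_class(rep_, "metrics_report")
  expect_identical(dim(rep_$per_class), c(2L, 3L))
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 100)
  expect_true(!is.na(rep_$auc))
  expect_output(print(rep_), "Accuracy")
})
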