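# Native base learners: gain-ratio tree, naive Bayes, k-NN, random tree and
# forest, plus the shared model contract.

test_that("the gain-ratio tree finds the perfect binary split", {
  ds <- emg_dataset(matrix(c(1, 2, 3, 4), 4), factor(c("A", "A", "B", "B")))
  m <- train_gain_ratio_tree(ds)
  expect_identical(m$tree$feature[1], 0L)
  expect_equal(m$tree$threshold[1], 2.5)
  v <- oracle_split_value(ds$x, ds$y, 1, 2.5)
  expect_equal(v$gain, 1)
  expect_equal(v$gr, 1)
  expect_identical(as.character(predict(m, matrix(c(0, 9), 2))),
                   c("A", "B"))
})

test_that("a pure dataset yields a single-leaf tree", {
  ds <- emg_dataset(matrix(rnorm(10), 5), factor(rep("A", 5),
                                                 levels = c("A", "B")))
  m <- train_gain_ratio_tree(ds)
  expect_length(m$tree$feature, 1L)
  expect_identical(m$tree$feature[1], -1L)
  expect_true(all(predict(m, matrix(rnorm(6), 3)) == "A"))
})

test_that("identical feature rows with mixed labels become a majority leaf", {
  ds <- emg_dataset(matrix(1, 5, 2), factor(c("A", "A", "A", "B", "B")))
  m <- train_gain_ratio_tree(ds)
  expect_identical(m$tree$feature[1], -1L)
  expect_identical(as.character(predict(m, matrix(1, 1, 2))), "A")
})

test_that("root splits attain the exhaustive-enumeration optimum", {
  set.seed(51)
  for (trial in 1:100) {
    n <- sample(2:6, 1)
    d <- sample(1:2, 1)
    x <- matrix(round(runif(n * d), 1), n, d)
    y <- factor(sample(c("A", "B"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    ds <- emg_dataset(x, y)
    m <- train_gain_ratio_tree(ds)
    best <- oracle_root_split(x, y)
    if (is.null(best)) {
      expect_identical(m$tree$feature[1], -1L)
    } else {
      expect_gte(m$tree$feature[1], 0L)
      chosen <- oracle_split_value(x, y, m$tree$feature[1] + 1L,
                                   m$tree$threshold[1])
      expect_equal(chosen$gr, best$gr, tolerance = 1e-9)
    }
  }
})

test_that("duplicating all instances with halved weights keeps the tree", {
  set.seed(52)
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(sample(c("A", "B"), 20, replace = TRUE,
                     prob = c(0.6, 0.4)))
  m1 <- train_gain_ratio_tree(emg_dataset(x, y))
  m2 <- train_gain_ratio_tree(
    emg_dataset(rbind(x, x), c(y, y), weights = rep(0.5, 40)))
  expect_identical(m1$tree$feature, m2$tree$feature)
  expect_equal(m1$tree$threshold, m2$tree$threshold)
})

test_that("naive Bayes posteriors behave on symmetric and separated data", {
  x <- matrix(c(-1, -1, 1, 1), 4)
  y <- factor(c("A", "A", "B", "B"))
  m <- fit_learner(naive_bayes_spec(), emg_dataset(x, y))
  s <- predict(m, matrix(0, 1), type = "score")
  expect_equal(as.numeric(s), c(0.5, 0.5), tolerance = 1e-12)

  set.seed(53)
  x2 <- matrix(c(rnorm(20, -3, 0.5), rnorm(20, 3, 0.5)), 40)
  y2 <- factor(rep(c("A", "B"), each = 20))
  m2 <- fit_learner(naive_bayes_spec(), emg_dataset(x2, y2))
  s2 <- predict(m2, matrix(c(-3, 3), 2), type = "score")
  expect_gt(s2[1, 1], 0.99)
  expect_gt(s2[2, 2], 0.99)
})

test_that("naive Bayes priors dominate identical likelihoods", {
  set.seed(54)
  x <- matrix(rnorm(100, 0, 1), 100)
  y <- factor(c(rep("A", 90), rep("B", 10)))
  m <- fit_learner(naive_bayes_spec(), emg_dataset(x, y))
  expect_identical(as.character(predict(m, matrix(0, 1))), "A")
})

test_that("naive Bayes rejects datasets with a missing class", {
  x <- matrix(rnorm(4), 4)
  y <- factor(rep("A", 4), levels = c("A", "B"))
  expect_error(fit_learner(naive_bayes_spec(), emg_dataset(x, y)),
               "missing")
})

test_that("k-NN follows neighbour-majority with weighted votes", {
  ds <- emg_dataset(matrix(c(0, 1, 10), 3), factor(c("A", "A", "B")))
  expect_identical(
    as.character(predict(fit_learner(knn_spec(1), ds), matrix(0.4, 1))),
    "A")
  expect_identical(
    as.character(predict(fit_learner(knn_spec(3), ds), matrix(10, 1))),
    "A")
  expect_error(fit_learner(knn_spec(4), ds), "exceeds training size")
  # k = n predicts the global weighted majority everywhere
  set.seed(55)
  ds2 <- emg_dataset(matrix(rnorm(20), 20),
                     factor(sample(c("A", "B"), 20, TRUE,
                                   prob = c(0.7, 0.3))))
  maj <- names(which.max(tapply(ds2$w, ds2$y, sum)))
  p <- predict(fit_learner(knn_spec(20), ds2), matrix(rnorm(10), 10))
  expect_true(all(p == maj))
})

test_that("random tree with the full feature set equals the plain tree", {
  set.seed(56)
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(sample(c("A", "B"), 30, TRUE))
  m1 <- train_gain_ratio_tree(emg_dataset(x, y))
  m2 <- train_random_tree(emg_dataset(x, y),
                          random_tree_spec(features_per_split = 2),
                          seed = 1L)
  expect_identical(m1$tree, m2$tree)
})

test_that("random trees are seed-deterministic and seed-sensitive", {
  set.seed(57)
  x <- matrix(rnorm(200), 100, 2)
  x[, 2] <- x[, 1] + rnorm(100, 0, 1e-8)  # redundant feature pair
  y <- factor(ifelse(x[, 1] > 0, "A", "B"))
  ds <- emg_dataset(x, y)
  t1 <- train_random_tree(ds, random_tree_spec(features_per_split = 1),
                          seed = 7L)
  t2 <- train_random_tree(ds, random_tree_spec(features_per_split = 1),
                          seed = 7L)
  expect_identical(t1$tree, t2$tree)
  roots <- vapply(1:20, function(s) {
    train_random_tree(ds, random_tree_spec(features_per_split = 1),
                      seed = s)$tree$feature[1]
  }, integer(1))
  expect_gt(length(unique(roots)), 1L)
})

test_that("the forest votes sum to one and separate easy data", {
  set.seed(58)
  n <- 100
  x <- rbind(matrix(rnorm(2 * n, 0, 0.3), ncol = 2),
             matrix(rnorm(2 * n, 2, 0.3), ncol = 2))
  y <- factor(rep(c("A", "B"), each = n))
  train <- sample(2 * n, n)
  m <- train_random_forest(emg_dataset(x[train, ], y[train]),
                           random_forest_spec(25), seed = 3L)
  sc <- predict(m, x[-train, ], type = "score")
  expect_equal(rowSums(sc), rep(1, nrow(sc)))
  expect_gte(mean(predict(m, x[-train, ]) == y[-train]), 0.98)
})

test_that("a 1-tree forest without bootstrap equals a single random tree", {
  set.seed(59)
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(sample(c("A", "B"), 30, TRUE))
  ds <- emg_dataset(x, y)
  f <- train_random_forest(ds, random_forest_spec(1, bootstrap = FALSE),
                           seed = 4L)
  t <- train_random_tree(ds, random_tree_spec(), seed = 4L)
  expect_identical(f$trees[[1]], t$tree)
})

test_that("weight resampling is the identity for uniform weights", {
  expect_identical(weight_resample_indices(rep(1, 10)), 1:10)
  expect_identical(weight_resample_indices(rep(2.5, 7)), 1:7)
  idx <- weight_resample_indices(c(3, 1, 1, 1))
  expect_length(idx, 4L)
  expect_identical(sum(idx == 1L), 2L)
})

test_that("score vectors are valid distributions with argmax = predict", {
  set.seed(60)
  x <- matrix(rnorm(90), 45, 2)
  y <- factor(sample(c("Normal", "Myopathy", "Neuropathy"), 45, TRUE),
              levels = c("Normal", "Myopathy", "Neuropathy"))
  ds <- emg_dataset(x, y)
  q <- matrix(rnorm(20), 10, 2)
  specs <- list(knn_spec(3), naive_bayes_spec(), gain_ratio_tree_spec(),
                random_forest_spec(5))
  for (spec in specs) {
    m <- fit_learner(spec, ds, seed = 2L)
    sc <- predict(m, q, type = "score")
    expect_true(all(sc >= 0))
    expect_equal(rowSums(sc), rep(1, 10))
    lab <- predict(m, q)
    agree <- vapply(seq_len(10), function(i) {
      sc[i, as.integer(lab[i])] >= max(sc[i, ]) - 1e-12
    }, logical(1))
    expect_true(all(agree))
  }
})

test_that("standardization is fit on training data only", {
  set.seed(61)
  x <- matrix(rnorm(40, 100, 5), 20, 2)
  y <- factor(rep(c("A", "B"), 10))
  m <- fit_learner(knn_spec(3), emg_dataset(x, y))
  expect_false(is.null(m$standardizer))
  expect_equal(m$standardizer$mu, colMeans(x))
})
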