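# Committee meta-algorithms: bagging, AdaBoost.M1 weight dynamics, wagging,
# MultiBoost scheduling and degenerate equivalences, committee voting.

test_that("a constant base learner gives a constant committee", {
  set.seed(71)
  ds <- emg_dataset(matrix(rnorm(20), 10),
                    factor(sample(c("A", "B"), 10, TRUE)))
  cm <- bagging_train(constant_learner("A"), ds, T = 5, seed = 1L)
  expect_true(all(predict(cm, matrix(rnorm(12), 6)) == "A"))
})

test_that("bagging with T = 1 and no resampling equals the base model", {
  set.seed(72)
  ds <- emg_dataset(matrix(rnorm(80), 40, 2),
                    factor(sample(c("A", "B"), 40, TRUE)))
  cm <- bagging_train(random_tree_spec(features_per_split = 1), ds, T = 1,
                      seed = 5L, resample = FALSE)
  single <- fit_learner(random_tree_spec(features_per_split = 1), ds,
                        seed = 5L)
  expect_identical(cm$members[[1]]$tree, single$tree)
  expect_identical(cm$member_weights, 1)
})

test_that("bootstrap resamples contain about 63.2% distinct instances", {
  # measured through the real bagging path with a counting adapter
  n <- 1000L
  counts <- new.env()
  counts$fracs <- numeric(0)
  counter <- adapter_spec("counter",
                          fit = function(x, y, w) {
                            counts$fracs <- c(counts$fracs,
                                              length(unique(x[, 1])) / n)
                            list(levels = levels(y))
                          },
                          predict_class = function(state, x) {
                            factor(rep("A", nrow(x)),
                                   levels = state$levels)
                          },
                          supports_weights = TRUE, standardize = FALSE)
  ds <- emg_dataset(matrix(seq_len(n), n),
                    factor(rep(c("A", "B"), length.out = n)))
  bagging_train(counter, ds, T = 200, seed = 8L)
  expect_lt(abs(mean(counts$fracs) - (1 - exp(-1))), 0.01)
})

test_that("the AdaBoost weight update matches the worked arithmetic", {
  # 4 instances, uniform mass 0.25 each; the base learner misclassifies
  # exactly one -> eps = 1/4, beta = 1/3, masses become 1/2 and 1/6.
  x <- matrix(1:4, 4)
  y <- factor(c("A", "A", "A", "B"))
  ds <- emg_dataset(x, y)
  cm <- adaboost_m1_train(constant_learner("A"), ds, T = 5, seed = 1L)
  expect_length(cm$members, 1L)
  tr <- cm$boost_trace[[1]]
  expect_equal(tr$eps, 0.25)
  expect_equal(cm$member_weights[1], log(3))
  masses <- tr$weights / sum(tr$weights)
  expect_equal(masses, c(1 / 6, 1 / 6, 1 / 6, 1 / 2), tolerance = 1e-12)
  # round 2 repeats the constant prediction: eps = 0.5 -> stream stops
})

test_that("instance weights stay normalized after every accepted round", {
  set.seed(73)
  x <- matrix(rnorm(60), 60)
  y <- factor(ifelse(x[, 1] + rnorm(60, 0, 0.5) > 0, "A", "B"))
  ds <- emg_dataset(x, y)
  cm <- adaboost_m1_train(gain_ratio_tree_spec(max_depth = 1), ds, T = 8,
                          seed = 2L)
  for (tr in cm$boost_trace) {
    expect_lt(abs(sum(tr$weights) - 60), 1e-9)
  }
  expect_gt(length(cm$boost_trace), 1L)
})

test_that("a first round with error >= 1/2 falls back to the base model", {
  x <- matrix(1:4, 4)
  y <- factor(c("A", "A", "B", "B"))
  ds <- emg_dataset(x, y)
  expect_warning(
    cm <- adaboost_m1_train(constant_learner("A"), ds, T = 5, seed = 1L),
    "falling back")
  expect_length(cm$members, 1L)
  expect_identical(cm$member_weights, 1)
})

test_that("boosted stumps drive training error to zero on the toy set", {
  x <- matrix(1:10, 10)
  y <- factor(ifelse(1:10 <= 6, "A", "B"))
  y[2] <- "B"
  ds <- emg_dataset(x, y)
  cm <- adaboost_m1_train(gain_ratio_tree_spec(max_depth = 1), ds, T = 10,
                          seed = 3L)
  expect_identical(mean(predict(cm, x) != y), 0)
})

test_that("the boosting training error respects the exponential bound", {
  set.seed(74)
  x <- matrix(rnorm(80), 80)
  y <- factor(ifelse(x[, 1] + rnorm(80, 0, 0.3) > 0, "A", "B"))
  ds <- emg_dataset(x, y)
  cm <- adaboost_m1_train(gain_ratio_tree_spec(max_depth = 1), ds, T = 10,
                          seed = 4L)
  eps <- vapply(cm$boost_trace, `[[`, numeric(1), "eps")
  bound <- prod(2 * sqrt(eps * (1 - eps)))
  train_err <- mean(predict(cm, x) != y)
  expect_lte(train_err, bound + 1e-12)
})

test_that("wagging weights are positive, normalized, and seedable", {
  for (model in c("continuous_poisson", "gaussian")) {
    w <- wagging_weights(500, model, seed = 5L)
    expect_true(all(w > 0))
    expect_lt(abs(sum(w) - 500), 1e-10)
  }
  expect_identical(wagging_weights(10, "gaussian", noise_scale = 0,
                                   seed = 1L), rep(1, 10))
  raw <- wagging_weights(1e5, "continuous_poisson", seed = 6L,
                         normalize = FALSE)
  expect_lt(abs(mean(raw) - 1), 0.01)
})

test_that("the MultiBoost schedule partitions T into near-equal blocks", {
  expect_identical(wpemg:::multiboost_schedule(10), c(3L, 2L, 3L, 2L))
  expect_identical(wpemg:::multiboost_schedule(4), c(2L, 2L))
  expect_identical(wpemg:::multiboost_schedule(10, 1), 10L)
  expect_identical(wpemg:::multiboost_schedule(10, 10), rep(1L, 10))
  expect_identical(sum(wpemg:::multiboost_schedule(17)), 17L)
  expect_error(wpemg:::multiboost_schedule(5, 6), "n_subcommittees")
})

test_that("MultiBoost degenerates to AdaBoost without wagging restarts", {
  set.seed(75)
  x <- matrix(rnorm(60), 60)
  y <- factor(ifelse(x[, 1] + rnorm(60, 0, 0.5) > 0, "A", "B"))
  ds <- emg_dataset(x, y)
  ada <- adaboost_m1_train(gain_ratio_tree_spec(max_depth = 1), ds, T = 6,
                           seed = 9L)
  mb <- multiboost_train(gain_ratio_tree_spec(max_depth = 1), ds, T = 6,
                         n_subcommittees = 1, seed = 9L,
                         wagging_noise = "none")
  expect_identical(length(mb$members), length(ada$members))
  expect_equal(mb$member_weights, ada$member_weights)
  for (i in seq_along(mb$members)) {
    expect_identical(mb$members[[i]]$tree, ada$members[[i]]$tree)
  }
})

test_that("MultiBoost with one-round blocks behaves as wagging alone", {
  set.seed(76)
  x <- matrix(rnorm(80), 40, 2)
  y <- factor(sample(c("A", "B"), 40, TRUE))
  ds <- emg_dataset(x, y)
  mb <- multiboost_train(gain_ratio_tree_spec(), ds, T = 5,
                         n_subcommittees = 5, seed = 10L)
  expect_lte(length(mb$members), 5L)
  expect_gte(length(mb$members), 1L)
})

test_that("committee voting weights votes and breaks ties by class order", {
  ds <- emg_dataset(matrix(1:2, 2), factor(c("A", "B")))
  mA <- fit_learner(constant_learner("A"), ds)
  mB <- fit_learner(constant_learner("B"), ds)
  cm <- wpemg:::new_committee(list(mA, mA, mB), c(1, 1, 1), "bagging", 3,
                              c("A", "B"))
  out <- committee_predict(cm, matrix(0, 1))
  expect_identical(as.character(out$label), "A")
  expect_equal(as.numeric(out$scores), c(2 / 3, 1 / 3))

  cm2 <- wpemg:::new_committee(list(mA, mB), c(0.1, 5), "bagging", 2,
                               c("A", "B"))
  expect_identical(as.character(predict(cm2, matrix(0, 1))), "B")

  cm3 <- wpemg:::new_committee(list(mB), 2, "bagging", 1, c("A", "B"))
  expect_equal(as.numeric(predict(cm3, matrix(0, 1), type = "score")),
               c(0, 1))

  # equal vote mass resolves to the smallest class index
  cm4 <- wpemg:::new_committee(list(mA, mB), c(1, 1), "bagging", 2,
                               c("A", "B"))
  expect_identical(as.character(predict(cm4, matrix(0, 1))), "A")

  cm_empty <- wpemg:::new_committee(list(), numeric(0), "bagging", 0,
                                    c("A", "B"))
  expect_error(committee_predict(cm_empty, matrix(0, 1)), "empty committee")
})

test_that("ensemble trainers are pure functions of (data, spec, seed)", {
  set.seed(77)
  x <- matrix(rnorm(80), 40, 2)
  y <- factor(sample(c("A", "B"), 40, TRUE))
  ds <- emg_dataset(x, y)
  for (trainer in list(
    function(s) bagging_train(random_tree_spec(), ds, T = 3, seed = s),
    function(s) adaboost_m1_train(random_tree_spec(), ds, T = 3, seed = s),
    function(s) multiboost_train(random_tree_spec(), ds, T = 4, seed = s))) {
    c1 <- trainer(13L)
    c2 <- trainer(13L)
    expect_equal(c1$member_weights, c2$member_weights)
    q <- matrix(rnorm(10), 5)
    expect_identical(predict(c1, q), predict(c2, q))
  }
})
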