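## R surface over the compiled gain-ratio tree: deterministic C4.5-style tree,
## random tree (fresh feature subset per node) and random forest.

tree_max_depth <- function(max_depth) {
  if (is.infinite(max_depth)) 0L else as.integer(max_depth)
}

fit_tree_model <- function(spec, dataset, mtry, seed = NULL) {
  d <- ncol(dataset$x)
  if (is.na(mtry)) {  # random tree: default ceil(sqrt(d))
    mtry <- if (is.null(spec$features_per_split)) ceiling(sqrt(d)) else
      as.integer(spec$features_per_split)
    if (mtry < 1L || mtry > d) {
      stop("features_per_split must be in 1..", d, call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
  }
  fit <- .fit_tree_cpp(dataset$x, as.integer(dataset$y) - 1L, dataset$w,
                       nlevels(dataset$y), as.integer(mtry),
                       tree_max_depth(spec$max_depth),
                       as.numeric(spec$min_leaf), spec$min_split)
  structure(list(tree = fit), class = "emg_tree")
}

#' Train a gain-ratio decision tree
#'
#' Binary C4.5-style tree on continuous features: at every node, each feature
#' contributes its best midpoint threshold by weighted information gain, and
#' among features whose gain is at least the mean candidate gain the split
#' with the highest gain ratio is chosen. Leaves predict the weighted-majority
#' class (tie: smallest class index). Unpruned by default.
#'
#' @param dataset An [emg_dataset()].
#' @param spec A [gain_ratio_tree_spec()].
#' @return Fitted `emg_tree` model.
#' @export
train_gain_ratio_tree <- function(dataset, spec = gain_ratio_tree_spec()) {
  fit_learner(spec, dataset)
}

#' Train a random tree
#'
#' Gain-ratio tree that considers a fresh uniformly-sampled feature subset of
#' size `features_per_split` (default `ceiling(sqrt(d))`) at every node.
#' Deterministic given `seed`.
#'
#' @inheritParams train_gain_ratio_tree
#' @param spec A [random_tree_spec()].
#' @param seed Integer seed.
#' @return Fitted `emg_tree` model.
#' @export
train_random_tree <- function(dataset, spec = random_tree_spec(), seed = 1L) {
  fit_learner(spec, dataset, seed = seed)
}

#' @export
model_scores.emg_tree <- function(model, newdata) {
  x <- prepare_newdata(model, newdata)
  .predict_tree_cpp(model$tree, x)$scores
}

fit_forest <- function(spec, dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset$x)
  d <- ncol(dataset$x)
  mtry <- if (is.null(spec$features_per_split)) ceiling(sqrt(d)) else
    as.integer(spec$features_per_split)
  trees <- vector("list", spec$n_trees)
  for (t in seq_len(spec$n_trees)) {
    ds <- dataset
    if (isTRUE(spec$bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE, prob = dataset$w)
      ds <- emg_dataset(dataset$x[idx, , drop = FALSE], dataset$y[idx])
    }
    trees[[t]] <- .fit_tree_cpp(ds$x, as.integer(ds$y) - 1L, ds$w,
                                nlevels(ds$y), mtry,
                                tree_max_depth(spec$max_depth),
                                as.numeric(spec$min_leaf), spec$min_split)
  }
  structure(list(trees = trees), class = "emg_forest")
}

#' Train a random forest
#'
#' `n_trees` random trees, each fit on a bootstrap resample of size `n` drawn
#' with replacement with probabilities proportional to the instance weights.
#' Prediction is the unweighted plurality vote; scores are vote fractions.
#'
#' @inheritParams train_random_tree
#' @param spec A [random_forest_spec()].
#' @return Fitted `emg_forest` model.
#' @export
train_random_forest <- function(dataset, spec = random_forest_spec(),
                                seed = 1L) {
  fit_learner(spec, dataset, seed = seed)
}

#' @export
model_scores.emg_forest <- function(model, newdata) {
  x <- prepare_newdata(model, newdata)
  K <- length(model$class_levels)
  votes <- matrix(0, nrow(x), K)
  for (tr in model$trees) {
    p <- .predict_tree_cpp(tr, x)$pred
    votes[cbind(seq_len(nrow(x)), p + 1L)] <-
      votes[cbind(seq_len(nrow(x)), p + 1L)] + 1
  }
  votes / rowSums(votes)
}
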