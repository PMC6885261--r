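## Base-learner contract and the native learners that do not need compiled
## code (Gaussian naive Bayes, k-nearest neighbours, adapters).
##
## Every fitted model is an S3 object with a `predict` method supporting
## `type = "class"` (labels) and `type = "score"` (per-class probabilities
## summing to 1; argmax with smallest-class-index tie-break equals the label).

#' Base-learner specification
#'
#' Constructors for the learner specs understood by [fit_learner()] and the
#' ensemble trainers.
#'
#' @param k Neighbour count for k-NN.
#' @param max_depth,min_leaf,min_split Tree growth limits (`max_depth = Inf`
#'   grows unpruned trees; `min_leaf` is the minimum total instance weight per
#'   leaf).
#' @param features_per_split Features considered at each random-tree node
#'   (default `ceiling(sqrt(d))`).
#' @param n_trees Forest size.
#' @param bootstrap Whether forest trees are fit on bootstrap resamples
#'   (default `TRUE`).
#' @param standardize Z-score features on training data (default `TRUE` for
#'   k-NN and adapters, `FALSE` for trees and naive Bayes).
#' @param fit,predict_class,predict_score Adapter functions: `fit(x, y, w)`
#'   returns opaque state; `predict_class(state, x)` returns labels;
#'   `predict_score(state, x)` (optional) returns a score matrix.
#' @param supports_weights Whether the adapter consumes instance weights; if
#'   `FALSE` weighted fits go through [weight_resample_indices()].
#' @name learner_specs
#' @return A `learner_spec` object.
NULL

new_learner_spec <- function(name, supports_weights, standardize, ...) {
  structure(list(name = name, supports_weights = supports_weights,
                 standardize = standardize, ...),
            class = "learner_spec")
}

#' @rdname learner_specs
#' @export
knn_spec <- function(k = 5L, standardize = TRUE) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  new_learner_spec("knn", supports_weights = TRUE, standardize = standardize,
                   k = k)
}

#' @rdname learner_specs
#' @export
naive_bayes_spec <- function(standardize = FALSE) {
  new_learner_spec("naive_bayes", supports_weights = TRUE,
                   standardize = standardize)
}

#' @rdname learner_specs
#' @export
gain_ratio_tree_spec <- function(max_depth = Inf, min_leaf = 1,
                                 min_split = 2L, standardize = FALSE) {
  new_learner_spec("gain_ratio_tree", supports_weights = TRUE,
                   standardize = standardize, max_depth = max_depth,
                   min_leaf = min_leaf, min_split = as.integer(min_split))
}

#' @rdname learner_specs
#' @export
random_tree_spec <- function(features_per_split = NULL, max_depth = Inf,
                             min_leaf = 1, min_split = 2L,
                             standardize = FALSE) {
  new_learner_spec("random_tree", supports_weights = TRUE,
                   standardize = standardize,
                   features_per_split = features_per_split,
                   max_depth = max_depth, min_leaf = min_leaf,
                   min_split = as.integer(min_split))
}

#' @rdname learner_specs
#' @export
random_forest_spec <- function(n_trees = 25L, features_per_split = NULL,
                               max_depth = Inf, min_leaf = 1, min_split = 2L,
                               bootstrap = TRUE, standardize = FALSE) {
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  new_learner_spec("random_forest", supports_weights = TRUE,
                   standardize = standardize, n_trees = n_trees,
                   features_per_split = features_per_split,
                   max_depth = max_depth, min_leaf = min_leaf,
                   min_split = as.integer(min_split), bootstrap = bootstrap)
}

#' @rdname learner_specs
#' @export
adapter_spec <- function(name, fit, predict_class, predict_score = NULL,
                         supports_weights = FALSE, standardize = TRUE) {
  stopifnot(is.function(fit), is.function(predict_class))
  new_learner_spec(paste0("adapter:", name), supports_weights = supports_weights,
                   standardize = standardize, fit = fit,
                   predict_class = predict_class,
                   predict_score = predict_score)
}

#' Fit a base learner on a (possibly weighted) dataset
#'
#' Dispatches on the spec name. Learners that do not support instance weights
#' are fit on a deterministic weight-proportional resample
#' ([weight_resample_indices()]); with uniform weights that is the identity.
#'
#' @param spec A `learner_spec`.
#' @param dataset An [emg_dataset()].
#' @param seed Optional integer seed (used by the randomized learners).
#' @return A fitted model (class `emg_model` plus a learner-specific class).
#' @export
fit_learner <- function(spec, dataset, seed = NULL) {
  stopifnot(inherits(spec, "learner_spec"), inherits(dataset, "emg_dataset"))
  if (!spec$supports_weights && diff(range(dataset$w)) > 1e-12) {
    idx <- weight_resample_indices(dataset$w)
    dataset <- emg_dataset(dataset$x[idx, , drop = FALSE], dataset$y[idx])
  }
  std <- NULL
  if (isTRUE(spec$standardize)) {
    std <- fit_standardizer(dataset$x)
    dataset$x <- apply_standardizer(std, dataset$x)
  }
  model <- switch(
    sub(":.*", "", spec$name),
    knn = fit_knn(spec, dataset),
    naive_bayes = fit_naive_bayes(spec, dataset),
    gain_ratio_tree = fit_tree_model(spec, dataset, mtry = 0L, seed = seed),
    random_tree = fit_tree_model(spec, dataset, mtry = NA, seed = seed),
    random_forest = fit_forest(spec, dataset, seed = seed),
    adapter = fit_adapter(spec, dataset),
    stop("unknown learner '", spec$name, "'", call. = FALSE))
  model$standardizer <- std
  model$class_levels <- dataset$class_levels
  model$spec <- spec
  class(model) <- c(class(model), "emg_model")
  model
}

# ---- shared prediction plumbing --------------------------------------------

prepare_newdata <- function(model, newdata) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(model$standardizer)) {
    x <- apply_standardizer(model$standardizer, x)
  }
  x
}

# Argmax with smallest-class-index tie-break.
score_to_label <- function(scores, class_levels) {
  idx <- apply(scores, 1L, function(s) which(s >= max(s) - 1e-12)[1L])
  factor(class_levels[idx], levels = class_levels)
}

#' Per-class scores of a fitted model
#'
#' @param model An `emg_model` or `emg_committee`.
#' @param newdata Feature matrix (instances x d).
#' @return Numeric matrix (instances x classes), rows nonnegative and summing
#'   to 1, columns in the model's class order.
#' @export
model_scores <- function(model, newdata) UseMethod("model_scores")

#' @export
predict.emg_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  scores <- model_scores(object, newdata)
  if (type == "score") return(scores)
  score_to_label(scores, object$class_levels)
}

# ---- Gaussian naive Bayes ---------------------------------------------------

fit_naive_bayes <- function(spec, dataset) {
  y <- dataset$y
  counts <- tapply(dataset$w, y, sum)
  if (any(is.na(counts) | counts <= 0)) {
    stop("every class must be present in the training data; missing: ",
         paste(levels(y)[is.na(counts) | counts <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dataset$x) < 2L) stop("need at least 2 instances", call. = FALSE)
  K <- nlevels(y)
  d <- ncol(dataset$x)
  mu <- matrix(0, K, d)
  var_ <- matrix(0, K, d)
  for (c in seq_len(K)) {
    rows <- which(as.integer(y) == c)
    w <- dataset$w[rows]
    xc <- dataset$x[rows, , drop = FALSE]
    mu[c, ] <- colSums(xc * w) / sum(w)
    var_[c, ] <- colSums(sweep(xc, 2L, mu[c, ])^2 * w) / sum(w)
  }
  var_[var_ < 1e-9] <- 1e-9
  structure(list(prior = as.numeric(counts / sum(counts)), mu = mu,
                 var = var_),
            class = "emg_naive_bayes")
}

#' @export
model_scores.emg_naive_bayes <- function(model, newdata) {
  x <- prepare_newdata(model, newdata)
  K <- length(model$prior)
  logp <- matrix(log(model$prior), nrow(x), K, byrow = TRUE)
  for (c in seq_len(K)) {
    ll <- -0.5 * (sweep(x, 2L, model$mu[c, ])^2 %*% (1 / model$var[c, ])) -
      0.5 * sum(log(2 * pi * model$var[c, ]))
    logp[, c] <- logp[, c] + as.numeric(ll)
  }
  m <- apply(logp, 1L, max)
  p <- exp(logp - m)
  p / rowSums(p)
}

# ---- k-nearest neighbours ---------------------------------------------------

fit_knn <- function(spec, dataset) {
  if (spec$k > nrow(dataset$x)) {
    stop("k = ", spec$k, " exceeds training size n = ", nrow(dataset$x),
         call. = FALSE)
  }
  structure(list(x = dataset$x, y = dataset$y, w = dataset$w, k = spec$k),
            class = "emg_knn")
}

#' @export
model_scores.emg_knn <- function(model, newdata) {
  x <- prepare_newdata(model, newdata)
  K <- nlevels(model$y)
  train <- model$x
  # squared Euclidean distances via the expansion trick, chunked for memory
  tr_sq <- rowSums(train^2)
  n <- nrow(x)
  scores <- matrix(0, n, K)
  chunk <- max(1L, floor(2e7 / nrow(train)))
  yi <- as.integer(model$y)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xs <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), tr_sq, "+") - 2 * xs %*% t(train)
    for (i in seq_len(e - s + 1L)) {
      nb <- order(d2[i, ])[seq_len(model$k)]
      wv <- tapply(model$w[nb], factor(yi[nb], levels = seq_len(K)), sum)
      wv[is.na(wv)] <- 0
      scores[s + i - 1L, ] <- wv / sum(wv)
    }
  }
  scores
}

# ---- adapter ----------------------------------------------------------------

fit_adapter <- function(spec, dataset) {
  state <- if (spec$supports_weights) {
    spec$fit(dataset$x, dataset$y, dataset$w)
  } else {
    spec$fit(dataset$x, dataset$y, rep(1, nrow(dataset$x)))
  }
  structure(list(state = state, predict_class = spec$predict_class,
                 predict_score = spec$predict_score,
                 levels_ = dataset$class_levels),
            class = "emg_adapter")
}

#' @export
model_scores.emg_adapter <- function(model, newdata) {
  x <- prepare_newdata(model, newdata)
  K <- length(model$levels_)
  if (!is.null(model$predict_score)) {
    s <- model$predict_score(model$state, x)
    return(s / rowSums(s))
  }
  lab <- as.character(model$predict_class(model$state, x))
  s <- matrix(0, nrow(x), K)
  s[cbind(seq_len(nrow(x)), match(lab, model$levels_))] <- 1
  s
}
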