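## Stratified k-fold cross-validation over a learner / ensemble pipeline.

#' Pipeline specification for cross-validation
#'
#' Pairs a base-learner spec with an optional ensemble method.
#'
#' @param learner A `learner_spec`.
#' @param ensemble `"none"`, `"bagging"`, `"adaboost"` or `"multiboost"`.
#' @param T Committee size (ignored for `"none"`).
#' @param n_subcommittees MultiBoost block count (default `ceiling(sqrt(T))`).
#' @param wagging_noise,noise_scale MultiBoost wagging options.
#' @return A `pipeline_spec` object.
#' @export
pipeline_spec <- function(learner, ensemble = c("none", "bagging", "adaboost",
                                                "multiboost"),
                          T = 10L, n_subcommittees = NULL,
                          wagging_noise = "continuous_poisson",
                          noise_scale = 2) {
  stopifnot(inherits(learner, "learner_spec"))
  structure(list(learner = learner, ensemble = match.arg(ensemble),
                 T = as.integer(T), n_subcommittees = n_subcommittees,
                 wagging_noise = wagging_noise, noise_scale = noise_scale),
            class = "pipeline_spec")
}

fit_pipeline <- function(spec, dataset, seed) {
  switch(spec$ensemble,
         none = fit_learner(spec$learner, dataset, seed = seed),
         bagging = bagging_train(spec$learner, dataset, spec$T, seed = seed),
         adaboost = adaboost_m1_train(spec$learner, dataset, spec$T,
                                      seed = seed),
         multiboost = multiboost_train(spec$learner, dataset, spec$T,
                                       spec$n_subcommittees, seed = seed,
                                       wagging_noise = spec$wagging_noise,
                                       noise_scale = spec$noise_scale))
}

#' Cross-validation configuration
#'
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed driving both fold assignment and per-fold
#'   training.
#' @param grouping `"frame"` (stratify individual instances, default) or
#'   `"recording"` (keep all frames of a recording in one fold; requires the
#'   table's `source_id` attribute).
#' @return A `cv_config` object.
#' @export
cv_config <- function(k_folds = 10L, seed = 1L,
                      grouping = c("frame", "recording")) {
  structure(list(k_folds = as.integer(k_folds), seed = as.integer(seed),
                 grouping = match.arg(grouping)),
            class = "cv_config")
}

# Fold assignment honouring the grouping mode.
cv_folds <- function(table, config) {
  labels <- ft_labels(table)
  if (config$grouping == "frame") {
    return(stratified_fold_indices(labels, config$k_folds, config$seed))
  }
  src <- attr(table, "source_id")
  if (is.null(src) || anyNA(src)) {
    stop("recording-grouped CV needs the table's source_id attribute",
         call. = FALSE)
  }
  recs <- unique(src)
  rec_labels <- labels[match(recs, src)]
  rec_folds <- stratified_fold_indices(rec_labels, config$k_folds,
                                       config$seed)
  lapply(rec_folds, function(ri) sort(which(src %in% recs[ri])))
}

#' Stratified k-fold cross-validation
#'
#' For every fold, trains the pipeline on the remaining folds (any
#' standardization is fit on training data only, inside the learner) and
#' scores the held-out fold. Out-of-fold predictions are pooled into the
#' final confusion matrix and [metrics_report()]; per-fold accuracies are
#' also reported. Deterministic given `config$seed`.
#'
#' @param spec A [pipeline_spec()] (or a bare `learner_spec`).
#' @param table A `feature_table`.
#' @param config A [cv_config()].
#' @return A `metrics_report`, with attributes `predictions` (pooled
#'   out-of-fold labels), `scores` and `fold_ids`.
#' @export
cross_validate <- function(spec, table, config = cv_config()) {
  if (inherits(spec, "learner_spec")) spec <- pipeline_spec(spec)
  stopifnot(inherits(spec, "pipeline_spec"))
  labels <- ft_labels(table)
  x <- ft_matrix(table)
  folds <- cv_folds(table, config)
  K <- nlevels(labels)
  n <- nrow(x)
  pred <- factor(rep(NA, n), levels = levels(labels))
  scores <- matrix(NA_real_, n, K)
  fold_ids <- integer(n)
  fold_acc <- numeric(length(folds))
  set.seed(config$seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    ds <- emg_dataset(x[train_idx, , drop = FALSE], labels[train_idx])
    model <- tryCatch(
      fit_pipeline(spec, ds, seed = fold_seeds[f]),
      error = function(e) stop("fold ", f, " failed: ", conditionMessage(e),
                               call. = FALSE))
    sc <- model_scores(model, x[test_idx, , drop = FALSE])
    scores[test_idx, ] <- sc
    pred[test_idx] <- score_to_label(sc, levels(labels))
    fold_ids[test_idx] <- f
    fold_acc[f] <- 100 * mean(pred[test_idx] == labels[test_idx])
  }
  cm <- confusion(labels, pred)
  rep_ <- metrics_report(cm, score_matrix = scores, true_labels = labels,
                         fold_accuracies = fold_acc)
  attr(rep_, "predictions") <- pred
  attr(rep_, "scores") <- scores
  attr(rep_, "fold_ids") <- fold_ids
  rep_
}
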