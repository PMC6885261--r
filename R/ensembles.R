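## Committee meta-algorithms: bagging, AdaBoost.M1 and MultiBoosting (wagging
## restarts around AdaBoost sub-committees), over any learner spec.

BETA_MIN <- 1e-10

new_committee <- function(members, member_weights, method, T, class_levels) {
  structure(list(members = members, member_weights = member_weights,
                 method = method, T = T, class_levels = class_levels),
            class = "emg_committee")
}

#' @export
print.emg_committee <- function(x, ...) {
  cat(sprintf("<emg_committee: %s, %d/%d members, weights [%s]>\n",
              x$method, length(x$members), x$T,
              paste(sprintf("%.3g", x$member_weights), collapse = ", ")))
  invisible(x)
}

#' Train a bagging committee
#'
#' Fits `T` base models, each on an independent bootstrap resample of size
#' `n`; all members vote with equal weight 1. A member whose fit fails is
#' skipped with a warning.
#'
#' @param spec A `learner_spec` for the base learner.
#' @param dataset An [emg_dataset()].
#' @param T Committee size (default 10).
#' @param seed Integer seed (the trainer is deterministic given it).
#' @param resample Set `FALSE` to fit every member on the full data (then
#'   `T = 1` equals the single base model).
#' @return An `emg_committee`.
#' @export
bagging_train <- function(spec, dataset, T = 10L, seed = 1L,
                          resample = TRUE) {
  stopifnot(T >= 1L)
  set.seed(seed)
  n <- nrow(dataset$x)
  members <- list()
  for (t in seq_len(T)) {
    ds <- dataset
    if (resample) {
      idx <- sample.int(n, n, replace = TRUE)
      ds <- emg_dataset(dataset$x[idx, , drop = FALSE], dataset$y[idx])
    }
    # member fits consume the trainer's RNG stream (seeded once above)
    m <- tryCatch(fit_learner(spec, ds),
                  error = function(e) {
                    warning("bagging round ", t, " skipped: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) members[[length(members) + 1L]] <- m
  }
  if (length(members) == 0L) stop("all bagging rounds failed", call. = FALSE)
  new_committee(members, rep(1, length(members)), "bagging", T,
                dataset$class_levels)
}

# One AdaBoost.M1 round on the current weights (uses the ambient RNG stream).
# Returns the fitted member, its weighted error and the updated weights, plus
# a verdict:
#   "accept"  - member kept, boosting continues
#   "perfect" - member kept with the capped weight, stream ends
#   "reject"  - member discarded (error >= 1/2), stream ends
adaboost_round <- function(spec, dataset, w) {
  n <- nrow(dataset$x)
  ds <- emg_dataset(dataset$x, dataset$y, weights = w)
  model <- fit_learner(spec, ds)
  pred <- predict(model, dataset$x)
  wrong <- pred != dataset$y
  eps <- sum(w[wrong]) / sum(w)
  if (eps >= 0.5) {
    return(list(verdict = "reject", model = model, eps = eps, w = w))
  }
  if (eps == 0) {
    return(list(verdict = "perfect", model = model, eps = eps, w = w,
                alpha = log(1 / BETA_MIN)))
  }
  beta <- eps / (1 - eps)
  w[!wrong] <- w[!wrong] * beta
  w <- w * (n / sum(w))
  list(verdict = "accept", model = model, eps = eps, w = w,
       alpha = log(1 / beta))
}

#' Train an AdaBoost.M1 committee
#'
#' Starts from the dataset's instance weights (uniform by default) and runs up
#' to `T` boosting rounds. After each round with weighted error `eps` in
#' (0, 0.5), correctly classified instances are down-weighted by
#' `beta = eps / (1 - eps)`, weights are renormalized to sum `n`, and the
#' member votes with weight `log(1 / beta)`. A round with `eps >= 0.5` is
#' discarded and stops boosting; `eps = 0` keeps the member with a capped
#' weight `log(1 / 1e-10)` and stops. If the very first member is rejected the
#' committee falls back to the single unweighted base model with a warning.
#'
#' @inheritParams bagging_train
#' @return An `emg_committee`.
#' @export
adaboost_m1_train <- function(spec, dataset, T = 10L, seed = 1L) {
  stopifnot(T >= 1L)
  if (nlevels(droplevels(dataset$y)) < 2L) {
    warning("single-class dataset: returning trivial one-member committee",
            call. = FALSE)
    m <- fit_learner(spec, dataset, seed = seed)
    return(new_committee(list(m), 1, "adaboost", T, dataset$class_levels))
  }
  set.seed(seed)
  w <- dataset$w
  members <- list()
  weights <- numeric(0)
  trace <- list()
  for (t in seq_len(T)) {
    rd <- adaboost_round(spec, dataset, w)
    if (rd$verdict == "reject") {
      if (length(members) == 0L) {
        warning("first boosting round had weighted error >= 1/2; ",
                "falling back to the unweighted base model", call. = FALSE)
        set.seed(seed)
        base <- fit_learner(spec, emg_dataset(dataset$x, dataset$y))
        return(new_committee(list(base), 1, "adaboost", T,
                             dataset$class_levels))
      }
      break
    }
    members[[length(members) + 1L]] <- rd$model
    weights <- c(weights, rd$alpha)
    w <- rd$w
    trace[[length(trace) + 1L]] <- list(round = t, eps = rd$eps,
                                        weights = w)
    if (rd$verdict == "perfect") break
  }
  cmte <- new_committee(members, weights, "adaboost", T,
                        dataset$class_levels)
  # per-round weighted error and post-update instance weights, for
  # inspection of the boosting dynamics
  cmte$boost_trace <- trace
  cmte
}

#' Wagging instance weights
#'
#' Random positive weights renormalized to sum `n`. The continuous-Poisson
#' model draws `-log(U)` with `U ~ Uniform(0, 1)` (Webb's MultiBoost
#' convention); the Gaussian model draws `max(0, 1 + N(0, noise_scale))` with
#' zeros floored at 1e-10 (Bauer-Kohavi). `"none"` returns uniform weights.
#'
#' @param n Number of instances.
#' @param noise_model `"continuous_poisson"`, `"gaussian"` or `"none"`.
#' @param noise_scale Gaussian noise standard deviation (default 2).
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @param normalize Renormalize to sum `n` (default `TRUE`; `FALSE` exposes
#'   the raw positive draws).
#' @return Positive weights of length `n` summing to `n` (when normalized).
#' @export
wagging_weights <- function(n, noise_model = c("continuous_poisson",
                                               "gaussian", "none"),
                            noise_scale = 2, seed = NULL, normalize = TRUE) {
  noise_model <- match.arg(noise_model)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  w <- switch(noise_model,
              continuous_poisson = -log(runif(n)),
              gaussian = pmax(0, 1 + rnorm(n, 0, noise_scale)),
              none = rep(1, n))
  w[w <= 0] <- BETA_MIN
  if (normalize) w * (n / sum(w)) else w
}

# Sub-committee block sizes: ceil(sqrt(T)) blocks ending at ceil(k*T/n_sub).
multiboost_schedule <- function(T, n_subcommittees = NULL) {
  n_sub <- if (is.null(n_subcommittees)) ceiling(sqrt(T)) else
    as.integer(n_subcommittees)
  if (n_sub < 1L || n_sub > T) {
    stop("n_subcommittees must be in 1..T", call. = FALSE)
  }
  ends <- as.integer(ceiling(seq_len(n_sub) * T / n_sub))
  diff(c(0L, ends))
}

#' Train a MultiBoosting committee
#'
#' `T` boosting rounds partitioned into `n_subcommittees` contiguous blocks
#' (default `ceiling(sqrt(T))`, block ends at `ceiling(k T / n_sub)`). At the
#' start of each block the instance weights are reset by [wagging_weights()];
#' within a block AdaBoost.M1 updates run as usual, except that a round with
#' error `>= 0.5` or `= 0` ends only the current block. All accepted members
#' vote with weight `log(1 / beta)`.
#'
#' With `n_subcommittees = 1` and `wagging_noise = "none"` the trainer
#' reproduces [adaboost_m1_train()] member by member.
#'
#' @inheritParams bagging_train
#' @param n_subcommittees Number of wagging restarts (default
#'   `ceiling(sqrt(T))`).
#' @param wagging_noise Noise model passed to [wagging_weights()].
#' @param noise_scale Gaussian noise scale.
#' @return An `emg_committee`.
#' @export
multiboost_train <- function(spec, dataset, T = 10L, n_subcommittees = NULL,
                             seed = 1L,
                             wagging_noise = "continuous_poisson",
                             noise_scale = 2) {
  stopifnot(T >= 1L)
  sizes <- multiboost_schedule(T, n_subcommittees)
  set.seed(seed)
  n <- nrow(dataset$x)
  members <- list()
  weights <- numeric(0)
  for (b in seq_along(sizes)) {
    # first block without noise keeps the dataset's own weights, so the
    # degenerate configuration reproduces adaboost_m1_train exactly
    w <- if (wagging_noise == "none" && b == 1L) dataset$w else
      wagging_weights(n, wagging_noise, noise_scale)
    for (j in seq_len(sizes[b])) {
      rd <- adaboost_round(spec, dataset, w)
      if (rd$verdict == "reject") break
      members[[length(members) + 1L]] <- rd$model
      weights <- c(weights, rd$alpha)
      w <- rd$w
      if (rd$verdict == "perfect") break
    }
  }
  if (length(members) == 0L) {
    warning("no sub-committee accepted a member; ",
            "falling back to the unweighted base model", call. = FALSE)
    set.seed(seed)
    base <- fit_learner(spec, emg_dataset(dataset$x, dataset$y))
    return(new_committee(list(base), 1, "multiboost", T,
                         dataset$class_levels))
  }
  new_committee(members, weights, "multiboost", T, dataset$class_levels)
}

#' Committee prediction by weighted vote
#'
#' `score_c = sum_t weight_t 1[member_t predicts c] / sum_t weight_t`; the
#' label is the argmax with smallest-class-index tie-break.
#'
#' @param committee An `emg_committee`.
#' @param newdata Feature matrix.
#' @return List with `label` (factor) and `scores` (matrix).
#' @export
committee_predict <- function(committee, newdata) {
  stopifnot(inherits(committee, "emg_committee"))
  if (length(committee$members) == 0L) {
    stop("empty committee", call. = FALSE)
  }
  scores <- model_scores(committee, newdata)
  list(label = score_to_label(scores, committee$class_levels),
       scores = scores)
}

#' @export
model_scores.emg_committee <- function(model, newdata) {
  K <- length(model$class_levels)
  x <- as.matrix(newdata)
  votes <- matrix(0, nrow(x), K)
  for (t in seq_along(model$members)) {
    p <- as.integer(predict(model$members[[t]], x))
    votes[cbind(seq_len(nrow(x)), p)] <-
      votes[cbind(seq_len(nrow(x)), p)] + model$member_weights[t]
  }
  votes / sum(model$member_weights)
}

#' @export
predict.emg_committee <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  res <- committee_predict(object, newdata)
  if (type == "score") res$scores else res$label
}
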