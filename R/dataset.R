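## Weighted instance container shared by learners and ensembles.

#' Weighted classification dataset
#'
#' @param x Numeric matrix or data.frame of features (instances x d).
#' @param y Class labels (factor or character; levels default to the
#'   canonical class order).
#' @param weights Positive instance weights; normalized to sum to `n`
#'   (default: all 1).
#' @return Object of class `emg_dataset` with fields `x`, `y`, `w`,
#'   `class_levels`.
#' @export
emg_dataset <- function(x, y, weights = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- if (is.factor(y)) y else as_class_factor(y)
  n <- nrow(x)
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive, finite, one per instance", call. = FALSE)
  }
  weights <- weights * (n / sum(weights))
  structure(list(x = x, y = y, w = weights, class_levels = levels(y)),
            class = "emg_dataset")
}

#' Convert a feature table to a weighted dataset
#'
#' @param table A `feature_table` (see [extract_features()]).
#' @param weights Optional instance weights.
#' @return An [emg_dataset()].
#' @export
as_emg_dataset <- function(table, weights = NULL) {
  emg_dataset(ft_matrix(table), ft_labels(table), weights)
}

#' Deterministic weight-proportional resample
#'
#' Replicates instance indices in proportion to their weights using the
#' largest-remainder method, so the resample size equals `n` exactly and
#' uniform weights reproduce the identity resample. Used to fit weighted data
#' with base learners that do not support instance weights.
#'
#' @param weights Positive weights.
#' @return Integer vector of `length(weights)` instance indices (sorted).
#' @export
weight_resample_indices <- function(weights) {
  n <- length(weights)
  quota <- weights * (n / sum(weights))
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(-frac, seq_len(n))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sort(rep.int(seq_len(n), base))
}

# Standardization helper: fit on training data, apply anywhere.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}
apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2L, std$mu, "-"), 2L, std$sd, "/")
}
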