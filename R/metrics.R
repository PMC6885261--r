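## Confusion-matrix metrics: accuracy, per-class precision/recall/F, Cohen's
## kappa, rank-based one-vs-rest AUC, and stratified fold assignment.

#' Stratified fold indices
#'
#' Shuffles each class independently and deals its members round-robin across
#' folds, so per-fold class counts differ from perfect proportionality by at
#' most 1. Deterministic given `seed`.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` disjoint integer index vectors covering all instances.
#' @export
stratified_fold_indices <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  counts <- table(labels)
  counts <- counts[counts > 0]
  if (k == n) {  # leave-one-out: singleton folds, stratification is vacuous
    set.seed(seed)
    return(as.list(sample(n)))
  }
  if (any(counts < k)) {
    stop("class(es) rarer than k folds: ",
         paste(names(counts)[counts < k], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted, in the fixed class order.
#'
#' @param true_labels,predicted_labels Equal-length label vectors (factors
#'   share levels; characters are matched against the canonical class order).
#' @return Integer K x K matrix of class `emg_confusion`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (is.factor(true_labels)) {
    lv <- levels(true_labels)
    predicted_labels <- as_class_factor(as.character(predicted_labels), lv)
  } else {
    true_labels <- as_class_factor(true_labels)
    lv <- levels(true_labels)
    predicted_labels <- as_class_factor(as.character(predicted_labels), lv)
  }
  cm <- table(true = true_labels, predicted = predicted_labels)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = list(true = lv, predicted = lv))
  class(cm) <- c("emg_confusion", class(cm))
  cm
}

# One-vs-rest collapse of a confusion matrix for class index c.
ovr_counts <- function(cm, c) {
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Precision, recall and F-measure of one class
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2 precision recall / (precision + recall)`; 0/0 cases are defined as 0
#' with a warning.
#'
#' @param cm A confusion matrix from [confusion()].
#' @param class Class name or index.
#' @return Named vector `precision`, `recall`, `F`.
#' @export
precision_recall_f <- function(cm, class) {
  c_idx <- if (is.character(class)) match(class, rownames(cm)) else class
  o <- ovr_counts(cm, c_idx)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0) for class ", rownames(cm)[c_idx],
              "; set to 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(o["tp"], o["tp"] + o["fp"], "precision")
  recall <- safe_div(o["tp"], o["tp"] + o["fn"], "recall")
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = unname(precision), recall = unname(recall), F = unname(f))
}

#' Total classification accuracy (per cent)
#'
#' @param cm A confusion matrix.
#' @return `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' `K = (P0 - Pe) / (1 - Pe)` with `P0 = trace/N` and
#' `Pe = sum_c row_c * col_c / N^2`. The degenerate `Pe = 1` case (constant
#' truth and prediction) is defined as 0 with a warning.
#'
#' @param cm A confusion matrix.
#' @return List-free numeric kappa; attributes `P0` and `Pe` carry the
#'   agreement components.
#' @export
kappa_statistic <- function(cm) {
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  p0 <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  k <- if (1 - pe <= 0) {
    warning("degenerate chance agreement (Pe = 1): kappa set to 0",
            call. = FALSE)
    0
  } else {
    (p0 - pe) / (1 - pe)
  }
  structure(k, P0 = p0, Pe = pe)
}

#' One-vs-rest multiclass AUC
#'
#' Per-class AUC is computed from the rank-sum (Mann-Whitney) statistic on the
#' class's score column with half-credit for ties, then averaged across
#' classes weighted by class prevalence. Classes with no positive or no
#' negative instances are skipped with a warning.
#'
#' @param score_matrix Instances x classes score matrix (rows sum to 1;
#'   column order = class order).
#' @param true_labels Labels (factor over the same classes).
#' @return Prevalence-weighted average AUC.
#' @export
auc_ovr <- function(score_matrix, true_labels) {
  true_labels <- if (is.factor(true_labels)) true_labels else
    as_class_factor(true_labels)
  K <- nlevels(true_labels)
  if (nlevels(droplevels(true_labels)) < 2L) {
    stop("AUC needs at least two classes in the truth", call. = FALSE)
  }
  if (ncol(score_matrix) != K) {
    stop("score matrix has ", ncol(score_matrix), " columns for ", K,
         " classes", call. = FALSE)
  }
  aucs <- rep(NA_real_, K)
  prev <- as.numeric(table(true_labels)) / length(true_labels)
  for (c in seq_len(K)) {
    pos <- as.integer(true_labels) == c
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) {
      warning("class ", levels(true_labels)[c],
              " lacks positives or negatives; skipped in AUC", call. = FALSE)
      next
    }
    r <- rank(score_matrix[, c], ties.method = "average")
    aucs[c] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  ok <- !is.na(aucs)
  sum(aucs[ok] * prev[ok]) / sum(prev[ok])
}

#' Assemble the full metrics report
#'
#' @param cm Confusion matrix from [confusion()].
#' @param score_matrix Optional score matrix for AUC.
#' @param true_labels Labels matching `score_matrix` rows.
#' @param fold_accuracies Optional per-fold accuracy vector.
#' @return Object of class `metrics_report`: `accuracy` (per cent),
#'   `per_class` (precision/recall/F rows), `weighted` averages, `auc`,
#'   `kappa` (with `P0`/`Pe`), `confusion`, `fold_accuracies`.
#' @export
metrics_report <- function(cm, score_matrix = NULL, true_labels = NULL,
                           fold_accuracies = NULL) {
  K <- nrow(cm)
  per_class <- t(vapply(seq_len(K), function(c) precision_recall_f(cm, c),
                        numeric(3)))
  rownames(per_class) <- rownames(cm)
  prev <- rowSums(cm) / sum(cm)
  weighted <- colSums(per_class * prev)
  auc <- if (!is.null(score_matrix)) auc_ovr(score_matrix, true_labels) else
    NA_real_
  kap <- kappa_statistic(cm)
  structure(list(accuracy = accuracy(cm), per_class = per_class,
                 weighted = weighted, auc = auc,
                 kappa = as.numeric(kap), P0 = attr(kap, "P0"),
                 Pe = attr(kap, "Pe"), confusion = cm,
                 fold_accuracies = fold_accuracies),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%%   kappa: %.4f   AUC: %s\n", x$accuracy,
              x$kappa, if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc)))
  cat(sprintf("Weighted precision/recall/F: %.4f / %.4f / %.4f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["F"]))
  cat("Confusion (rows = truth):\n")
  print(unclass(x$confusion))
  if (!is.null(x$fold_accuracies)) {
    cat("Per-fold accuracy (%):",
        paste(sprintf("%.1f", x$fold_accuracies), collapse = " "), "\n")
  }
  invisible(x)
}
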