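## Per-subband statistical features and feature-table assembly.
##
## Six statistics summarise each subband's coefficient distribution: mean
## absolute value, average power, population standard deviation (divisor M, no
## Bessel correction), skewness and raw kurtosis (no -3 excess term), plus the
## ratio of absolute-mean sums between frequency-adjacent subbands. Degenerate
## cases (zero variance, zero ratio denominator) yield 0 with a warning so the
## feature matrix is always finite.

#' Subband summary statistics
#'
#' Computes the five per-subband statistics of a coefficient block: mean
#' absolute value, average power, population standard deviation, skewness and
#' raw (non-excess) kurtosis.
#'
#' @param coefficients Numeric vector of subband coefficients (or a subband
#'   list from [wpd_decompose()]).
#' @return Named numeric vector `meanabs`, `avgpower`, `std`, `skewness`,
#'   `kurtosis`. A zero-variance subband has `skewness` and `kurtosis`
#'   defined as 0 (with a warning).
#' @export
subband_stats <- function(coefficients) {
  y <- if (is.list(coefficients)) coefficients$coefficients else coefficients
  if (!is.numeric(y) || length(y) < 1L) {
    stop("subband must hold at least one numeric coefficient", call. = FALSE)
  }
  M <- length(y)
  mu <- mean(y)
  centred <- y - mu
  v <- sum(centred^2) / M
  s <- sqrt(v)
  if (s > 0) {
    z <- centred / s
    skew <- sum(z^3) / M
    kurt <- sum(z^4) / M
  } else {
    warning("zero-variance subband: skewness and kurtosis set to 0",
            call. = FALSE)
    skew <- 0
    kurt <- 0
  }
  c(meanabs = sum(abs(y)) / M, avgpower = sum(y^2) / M, std = s,
    skewness = skew, kurtosis = kurt)
}

#' Ratios of absolute coefficient sums between adjacent subbands
#'
#' For subbands in frequency order, `ratio[i]` is the sum of absolute
#' coefficients of subband `i` divided by that of subband `i + 1`.
#'
#' @param subbands List of subbands (from [wpd_decompose()]) or of numeric
#'   vectors, in frequency order.
#' @return Numeric vector of length `length(subbands) - 1`. A zero denominator
#'   yields 0 with a warning (features must stay finite).
#' @export
adjacent_ratios <- function(subbands) {
  sums <- vapply(subbands, function(s) {
    y <- if (is.list(s)) s$coefficients else s
    sum(abs(y))
  }, numeric(1))
  n <- length(sums)
  if (n < 2L) stop("need at least two subbands", call. = FALSE)
  num <- sums[-n]
  den <- sums[-1L]
  out <- numeric(n - 1L)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  if (any(!ok)) {
    warning("zero-denominator adjacent ratio set to 0", call. = FALSE)
  }
  out
}

# Internal: feature names for a config (stats grouped per subband in
# frequency order, then the adjacent ratios).
wpd_feature_names <- function(config) {
  stat_names <- c("meanabs", "avgpower", "std", "skewness", "kurtosis")
  levels_wanted <- if (config$subband_set == "terminal") config$level else
    seq_len(config$level)
  per_band <- character(0)
  ratio_names <- character(0)
  for (lev in levels_wanted) {
    nb <- 2^lev
    tags <- sprintf("L%d.S%02d", lev, 0:(nb - 1L))
    per_band <- c(per_band,
                  as.vector(vapply(tags, function(t) paste0(t, ".", stat_names),
                                   character(5))))
    ratio_names <- c(ratio_names,
                     sprintf("L%d.R%02d_%02d", lev, 0:(nb - 2L), 1:(nb - 1L)))
  }
  c(per_band, ratio_names)
}

#' Extract the wavelet-packet feature table from a set of frames
#'
#' Decomposes every frame with the configured wavelet packet transform and
#' assembles one feature row per frame: five statistics per subband (frequency
#' order) followed by the adjacent-subband ratios. With the defaults (level 4,
#' terminal subbands) that is 16 x 5 + 15 = 95 features.
#'
#' @param frames List of frames from [frame_signal()] (each with `samples`,
#'   `label`, `source_id`, `frame_index`), or a list of plain numeric vectors.
#' @param config A [wpd_config()].
#' @return A `data.frame` of class `feature_table`: feature columns, then a
#'   `label` factor column; attributes `feature_names`, `source_id` and
#'   `frame_index` carry provenance.
#' @export
extract_features <- function(frames, config = wpd_config()) {
  if (length(frames) == 0L) stop("no frames supplied", call. = FALSE)
  plain <- is.numeric(frames[[1L]])
  samp <- function(f) if (plain) f else f$samples
  lens <- vapply(frames, function(f) length(samp(f)), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("mixed frame lengths: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  feature_names <- wpd_feature_names(config)
  # subband ordering is identical for every frame; frequency order is
  # required for the adjacency ratios
  rows <- lapply(frames, function(f) {
    sb <- wpd_decompose(samp(f), config)
    lev <- vapply(sb, `[[`, integer(1), "level")
    stats <- unlist(lapply(sb, subband_stats), use.names = FALSE)
    ratios <- unlist(lapply(unique(lev), function(l) {
      adjacent_ratios(sb[lev == l])
    }), use.names = FALSE)
    c(stats, ratios)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names
  labels <- if (plain) rep(NA_character_, length(frames)) else
    vapply(frames, function(f) as.character(f$label), character(1))
  tab <- as.data.frame(mat)
  tab$label <- if (all(is.na(labels))) factor(rep(NA, nrow(tab)),
                                              levels = EMG_CLASSES) else
    as_class_factor(labels)
  attr(tab, "feature_names") <- feature_names
  attr(tab, "source_id") <- if (plain) rep(NA_character_, length(frames)) else
    vapply(frames, function(f) as.character(f$source_id), character(1))
  attr(tab, "frame_index") <- if (plain) rep(NA_integer_, length(frames)) else
    vapply(frames, function(f) as.integer(f$frame_index), integer(1))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Internal accessors working for both feature_table and plain data.frames
# with a trailing label column.
ft_feature_names <- function(table) {
  fn <- attr(table, "feature_names")
  if (!is.null(fn)) fn else setdiff(colnames(table),
                                    c("label", "recording_id", "frame_index"))
}
ft_matrix <- function(table) {
  as.matrix(table[, ft_feature_names(table), drop = FALSE])
}
ft_labels <- function(table) {
  if (!"label" %in% colnames(table)) stop("table has no label column",
                                          call. = FALSE)
  lab <- table$label
  if (is.factor(lab)) lab else as_class_factor(lab)
}
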