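# Independent oracles: brute-force filter-bank decomposition via explicit
# circulant matrices, and exhaustive-enumeration C4.5 split search.

# Analysis matrices for one filter-bank step by direct accumulation of the
# periodized convolution-and-downsample operator (independent of the
# package's tap-loop implementation).
oracle_step_matrix <- function(filt, N) {
  K <- N %/% 2L
  A <- matrix(0, K, N)
  for (k in 0:(K - 1L)) {
    for (l in seq_along(filt)) {
      j <- (2L * k + l - 1L) %% N
      A[k + 1L, j + 1L] <- A[k + 1L, j + 1L] + filt[l]
    }
  }
  A
}

# Full terminal decomposition at `level` in natural order via matrices.
oracle_wpd <- function(x, wavelet_name, level) {
  f <- wpd_filters(wavelet_name)
  nodes <- list(x)
  for (lev in seq_len(level)) {
    nxt <- list()
    for (nd in nodes) {
      Alo <- oracle_step_matrix(f$lo, length(nd))
      Ahi <- oracle_step_matrix(f$hi, length(nd))
      nxt <- c(nxt, list(as.numeric(Alo %*% nd), as.numeric(Ahi %*% nd)))
    }
    nodes <- nxt
  }
  nodes
}

# Weighted entropy in bits.
oracle_entropy <- function(w_by_class) {
  tot <- sum(w_by_class)
  p <- w_by_class[w_by_class > 0] / tot
  -sum(p * log2(p))
}

# Exhaustive-enumeration root split under the selection rule: per feature,
# the best midpoint threshold by weighted information gain; among features
# with gain >= mean candidate gain, maximize gain ratio. Returns NULL if no
# feature admits a split with positive gain.
oracle_root_split <- function(x, y, w = rep(1, nrow(x))) {
  x <- as.matrix(x)
  y <- as.integer(as.factor(y))
  K <- max(y)
  parent <- oracle_entropy(vapply(seq_len(K), function(c) sum(w[y == c]),
                                  numeric(1)))
  W <- sum(w)
  per_feature <- lapply(seq_len(ncol(x)), function(f) {
    vals <- sort(unique(x[, f]))
    if (length(vals) < 2L) return(NULL)
    best <- NULL
    for (i in seq_len(length(vals) - 1L)) {
      thr <- vals[i] + (vals[i + 1L] - vals[i]) / 2
      left <- x[, f] <= thr
      wl <- vapply(seq_len(K), function(c) sum(w[left & y == c]), numeric(1))
      wr <- vapply(seq_len(K), function(c) sum(w[!left & y == c]), numeric(1))
      gain <- parent - sum(wl) / W * oracle_entropy(wl) -
        sum(wr) / W * oracle_entropy(wr)
      pl <- sum(wl) / W
      si <- -pl * log2(pl) - (1 - pl) * log2(1 - pl)
      if (is.null(best) || gain > best$gain + 1e-15) {
        best <- list(feature = f, threshold = thr, gain = gain, si = si,
                     gr = if (si > 0) gain / si else 0)
      }
    }
    best
  })
  per_feature <- Filter(Negate(is.null), per_feature)
  if (length(per_feature) == 0L) return(NULL)
  gains <- vapply(per_feature, `[[`, numeric(1), "gain")
  mean_gain <- mean(gains)
  cands <- per_feature[gains >= mean_gain - 1e-12]
  grs <- vapply(cands, `[[`, numeric(1), "gr")
  best <- cands[[which.max(grs)]]
  if (best$gain <= 1e-12) return(NULL)
  best
}

# Gain and gain ratio of a given (feature, threshold) split, recomputed from
# scratch; used to judge whether the tree's chosen root split attains the
# oracle optimum.
oracle_split_value <- function(x, y, f, thr, w = rep(1, nrow(x))) {
  x <- as.matrix(x)
  y <- as.integer(as.factor(y))
  K <- max(y)
  parent <- oracle_entropy(vapply(seq_len(K), function(c) sum(w[y == c]),
                                  numeric(1)))
  W <- sum(w)
  left <- x[, f] <= thr
  wl <- vapply(seq_len(K), function(c) sum(w[left & y == c]), numeric(1))
  wr <- vapply(seq_len(K), function(c) sum(w[!left & y == c]), numeric(1))
  gain <- parent - sum(wl) / W * oracle_entropy(wl) -
    sum(wr) / W * oracle_entropy(wr)
  pl <- sum(wl) / W
  si <- if (pl <= 0 || pl >= 1) 0 else -pl * log2(pl) - (1 - pl) * log2(1 - pl)
  list(gain = gain, gr = if (si > 0) gain / si else 0)
}
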