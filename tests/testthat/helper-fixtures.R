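# Shared fixtures built in code.

# Constant-prediction adapter: always predicts `label`.
constant_learner <- function(label) {
  adapter_spec(paste0("const_", label),
               fit = function(x, y, w) list(label = label,
                                            levels = levels(y)),
               predict_class = function(state, x) {
                 factor(rep(state$label, nrow(x)), levels = state$levels)
               },
               supports_weights = TRUE, standardize = FALSE)
}

# Adapter that returns a fixed label sequence by row order of the training /
# query matrix (keyed on the first feature, which must uniquely identify
# instances).
lookup_learner <- function(key_values, key_labels, levels_) {
  adapter_spec("lookup",
               fit = function(x, y, w) list(),
               predict_class = function(state, x) {
                 factor(key_labels[match(x[, 1L], key_values)],
                        levels = levels_)
               },
               supports_weights = TRUE, standardize = FALSE)
}

# Two well-separated Gaussian classes in 2-D.
separable_table <- function(n_per_class = 60L, gap = 8, sd = 0.5,
                            seed = 11L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, 0, sd), ncol = 2),
             matrix(rnorm(2 * n_per_class, gap, sd), ncol = 2))
  tab <- as.data.frame(x)
  colnames(tab) <- c("f1", "f2")
  tab$label <- factor(rep(c("Normal", "Myopathy"), each = n_per_class),
                      levels = c("Normal", "Myopathy"))
  attr(tab, "feature_names") <- c("f1", "f2")
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Small random feature table with k balanced classes.
random_table <- function(n_per_class = 50L, d = 4L,
                         classes = c("Normal", "Myopathy", "Neuropathy"),
                         seed = 5L) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  tab <- as.data.frame(matrix(rnorm(n * d), n, d))
  colnames(tab) <- paste0("f", seq_len(d))
  tab$label <- factor(rep(classes, each = n_per_class), levels = classes)
  attr(tab, "feature_names") <- paste0("f", seq_len(d))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Tiny, fast simulation config for unit tests.
tiny_sim_config <- function(seed = 1L, fs = 4000, dur = 0.5) {
  simulation_config(sampling_rate_hz = fs, duration_s = dur,
                    bandpass_hz = c(5, fs / 2), seed = seed)
}
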