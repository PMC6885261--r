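## End-to-end orchestration from a single YAML config:
## simulate -> extract -> evaluate, with one global seed fanned out to
## per-stage seeds by fixed offsets (simulate +1, cv +2).

SEED_OFFSET_SIMULATE <- 1L
SEED_OFFSET_CV <- 2L

default_run_config <- function() {
  list(
    seed = 42L,
    output_dir = "wpemg_output",
    log_level = "info",
    simulate = list(n_recordings_per_class = 17L, sampling_rate_hz = 20000,
                    duration_s = 5, bandpass_low_hz = 5,
                    bandpass_high_hz = 10000),
    wpd = list(wavelet_name = "db4", level = 4L, extension_mode = "periodic",
               subband_set = "terminal", ordering = "frequency",
               frame_length = 2048L, overlap = 0L),
    learner = list(name = "random_forest", k = 5L, n_trees = 25L,
                   features_per_split = NULL, max_depth = NULL),
    ensemble = list(method = "adaboost", T = 10L, n_subcommittees = NULL,
                    wagging_noise = "continuous_poisson", noise_scale = 2),
    cv = list(k_folds = 10L, grouping = "frame")
  )
}

# Merge user keys over the defaults, rejecting unknown keys with their path.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]),
                                      full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with sections `simulate`, `wpd`, `learner`, `ensemble`, `cv`
#' plus global `seed`, `output_dir` and `log_level`. Unknown keys are
#' rejected; omitted keys take the documented defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: '", path, "'",
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    cfg <- merge_config(cfg, user)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

log_msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message("[wpemg] ", ...)
  }
}

#' Simulate the configured dataset and write it to disk
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return Path of the written manifest.
#' @export
cmd_simulate <- function(config = read_run_config()) {
  sim <- config$simulate
  sim_cfg <- simulation_config(
    sampling_rate_hz = sim$sampling_rate_hz, duration_s = sim$duration_s,
    bandpass_hz = c(sim$bandpass_low_hz, sim$bandpass_high_hz),
    seed = config$seed + SEED_OFFSET_SIMULATE)
  recs <- simulate_dataset(default_class_profiles(),
                           sim$n_recordings_per_class, sim_cfg)
  out_dir <- file.path(config$output_dir, "recordings")
  manifest <- write_recordings(recs, out_dir)
  counts <- table(vapply(recs, `[[`, character(1), "label"))
  log_msg(config, "simulated ", length(recs), " recordings (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ") -> ",
          manifest)
  manifest
}

#' Extract the wavelet-packet feature table from a manifest
#'
#' @param config A `run_config`.
#' @param manifest_path Manifest written by [cmd_simulate()] /
#'   [write_recordings()].
#' @return Path of the written feature CSV (an ARFF twin is written next to
#'   it).
#' @export
cmd_extract <- function(config = read_run_config(),
                        manifest_path = file.path(config$output_dir,
                                                  "recordings",
                                                  "manifest.csv")) {
  recs <- read_recordings(manifest_path)
  frames <- frame_recordings(recs, frame_length = config$wpd$frame_length,
                             overlap = config$wpd$overlap)
  wcfg <- wpd_config(config$wpd$wavelet_name, config$wpd$level,
                     config$wpd$extension_mode, config$wpd$subband_set,
                     config$wpd$ordering)
  table <- extract_features(frames, wcfg)
  counts <- table(ft_labels(table))
  log_msg(config, "extracted ", nrow(table), " x ",
          length(ft_feature_names(table)), " feature table (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir,
                                                 recursive = TRUE)
  csv_path <- file.path(config$output_dir, "features.csv")
  write_feature_table(table, csv_path, "csv")
  write_feature_table(table, file.path(config$output_dir, "features.arff"),
                      "arff")
  csv_path
}

learner_spec_from_config <- function(lc) {
  max_depth <- if (is.null(lc$max_depth)) Inf else lc$max_depth
  switch(lc$name,
         knn = knn_spec(k = lc$k),
         naive_bayes = naive_bayes_spec(),
         gain_ratio_tree = gain_ratio_tree_spec(max_depth = max_depth),
         random_tree = random_tree_spec(
           features_per_split = lc$features_per_split,
           max_depth = max_depth),
         random_forest = random_forest_spec(
           n_trees = lc$n_trees,
           features_per_split = lc$features_per_split,
           max_depth = max_depth),
         stop("unknown learner '", lc$name, "' in config", call. = FALSE))
}

# Deterministic JSON serialization of a metrics report.
report_to_json <- function(report, path) {
  payload <- list(
    accuracy = report$accuracy,
    kappa = report$kappa, P0 = report$P0, Pe = report$Pe,
    auc = report$auc,
    weighted = as.list(report$weighted),
    per_class = lapply(seq_len(nrow(report$per_class)), function(i) {
      as.list(report$per_class[i, ])
    }),
    confusion = unclass(report$confusion),
    fold_accuracies = report$fold_accuracies)
  names(payload$per_class) <- rownames(report$per_class)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Cross-validate the configured pipeline on a feature table
#'
#' Runs [cross_validate()] for the configured learner x ensemble combination,
#' writing a JSON report, a key/value text report and the confusion matrix as
#' CSV into the output directory.
#'
#' @param config A `run_config`.
#' @param feature_table_path CSV written by [cmd_extract()].
#' @return Named list of written report paths, with the `metrics_report` as
#'   attribute `report`.
#' @export
cmd_evaluate <- function(config = read_run_config(),
                         feature_table_path = file.path(config$output_dir,
                                                        "features.csv")) {
  table <- read_feature_table(feature_table_path)
  spec <- pipeline_spec(learner_spec_from_config(config$learner),
                        ensemble = config$ensemble$method,
                        T = config$ensemble$T,
                        n_subcommittees = config$ensemble$n_subcommittees,
                        wagging_noise = config$ensemble$wagging_noise,
                        noise_scale = config$ensemble$noise_scale)
  cv <- cv_config(config$cv$k_folds, seed = config$seed + SEED_OFFSET_CV,
                  grouping = config$cv$grouping)
  report <- cross_validate(spec, table, cv)
  tag <- paste0(config$learner$name, "_", config$ensemble$method)
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir,
                                                 recursive = TRUE)
  paths <- list(
    json = file.path(config$output_dir, paste0("report_", tag, ".json")),
    text = file.path(config$output_dir, paste0("report_", tag, ".txt")),
    confusion = file.path(config$output_dir,
                          paste0("confusion_", tag, ".csv")))
  report_to_json(report, paths$json)
  txt <- c(sprintf("learner: %s", config$learner$name),
           sprintf("ensemble: %s", config$ensemble$method),
           sprintf("accuracy_pct: %.10g", report$accuracy),
           sprintf("kappa: %.10g", report$kappa),
           sprintf("auc_weighted: %.10g", report$auc),
           sprintf("f_weighted: %.10g", report$weighted["F"]))
  writeLines(txt, paths$text)
  write.csv(as.data.frame(unclass(report$confusion)), paths$confusion)
  log_msg(config, tag, ": accuracy ", sprintf("%.2f%%", report$accuracy),
          ", kappa ", sprintf("%.3f", report$kappa))
  attr(paths, "report") <- report
  paths
}

#' Run the whole pipeline: simulate, extract, evaluate
#'
#' @param config A `run_config`.
#' @return The [cmd_evaluate()] result.
#' @export
cmd_run <- function(config = read_run_config()) {
  manifest <- cmd_simulate(config)
  table_path <- cmd_extract(config, manifest)
  cmd_evaluate(config, table_path)
}
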