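## Recording containers, delimited-text persistence and rectangular framing.
##
## Storage format: one numeric sample per line per recording, plus a CSV
## manifest `recording_id,path,sampling_rate_hz,label`. Samples are written
## with 17 significant digits so a round-trip reproduces every double exactly.
## Sample and frame indices are 0-based throughout.

UNLABELLED <- "unlabelled"

#' EMG recording container
#'
#' @param samples Finite numeric vector (millivolts).
#' @param sampling_rate_hz Sampling rate (> 0).
#' @param label Class label or `NA` for unlabelled recordings.
#' @param recording_id Identifier string.
#' @param seed Optional integer, the simulator seed that produced the samples.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate_hz, label = NA,
                          recording_id = "rec", seed = NA_integer_) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("samples must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0", call. = FALSE)
  }
  if (!is.na(label)) label <- match.arg(as.character(label), EMG_CLASSES)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 label = label, recording_id = as.character(recording_id),
                 seed = as.integer(seed)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording '%s': %d samples @ %g Hz (%.3f s), label %s>\n",
              x$recording_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              if (is.na(x$label)) UNLABELLED else x$label))
  invisible(x)
}

#' Write recordings and a manifest to a directory
#'
#' Each recording is stored as `<recording_id>.txt` (one sample per line, 17
#' significant digits) next to a `manifest.csv` with columns
#' `recording_id,path,sampling_rate_hz,label`. Unlabelled recordings store the
#' token `"unlabelled"`.
#'
#' @param recordings List of [emg_recording()]s (may be empty).
#' @param out_dir Output directory; created if missing.
#' @return Path of the written manifest, invisibly.
#' @export
write_recordings <- function(recordings, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", out_dir, "'", call. = FALSE)
  }
  rows <- lapply(recordings, function(rec) {
    stopifnot(inherits(rec, "emg_recording"))
    fname <- paste0(rec$recording_id, ".txt")
    writeLines(sprintf("%.17g", rec$samples), file.path(out_dir, fname))
    data.frame(recording_id = rec$recording_id, path = fname,
               sampling_rate_hz = rec$sampling_rate_hz,
               label = if (is.na(rec$label)) UNLABELLED else rec$label,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(recording_id = character(0), path = character(0),
               sampling_rate_hz = numeric(0), label = character(0))
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Read recordings listed in a manifest
#'
#' @param manifest_path CSV manifest with header
#'   `recording_id,path,sampling_rate_hz,label`; relative sample paths are
#'   resolved against the manifest's directory.
#' @return List of [emg_recording()]s (empty, with a warning, for an empty
#'   manifest).
#' @export
read_recordings <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: '", manifest_path, "'", call. = FALSE)
  }
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("recording_id", "path", "sampling_rate_hz", "label")
  missing <- setdiff(required, colnames(manifest))
  if (length(missing) > 0L) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no recordings", call. = FALSE)
    return(list())
  }
  if (any(is.na(manifest$sampling_rate_hz))) {
    stop("manifest has missing sampling_rate_hz entries", call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$path[i])
    if (!file.exists(p)) {
      stop("sample file not found: '", manifest$path[i], "'", call. = FALSE)
    }
    lines <- readLines(p)
    samples <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(samples) & !is.na(lines))
    if (length(bad) > 0L) {
      stop("non-numeric sample in '", p, "' at line ", bad[1L], ": '",
           lines[bad[1L]], "'", call. = FALSE)
    }
    lab <- manifest$label[i]
    emg_recording(samples, manifest$sampling_rate_hz[i],
                  label = if (identical(lab, UNLABELLED) || is.na(lab)) NA else lab,
                  recording_id = manifest$recording_id[i])
  })
}

#' Cut a recording into fixed-length rectangular frames
#'
#' Contiguous frames start at sample 0 (configurable offset); any trailing
#' remainder shorter than one frame is discarded. Each frame inherits the
#' recording's label.
#'
#' @param recording An [emg_recording()].
#' @param frame_length Samples per frame (default 2048).
#' @param overlap Samples shared by consecutive frames (default 0,
#'   non-overlapping).
#' @param offset First sample index used (0-based, default 0).
#' @return List of frames; each has `samples`, `label`, `source_id` and
#'   0-based `frame_index`.
#' @export
frame_signal <- function(recording, frame_length = 2048L, overlap = 0L,
                         offset = 0L) {
  stopifnot(inherits(recording, "emg_recording"))
  frame_length <- as.integer(frame_length)
  overlap <- as.integer(overlap)
  offset <- as.integer(offset)
  if (frame_length < 2L) stop("frame_length must be >= 2", call. = FALSE)
  if (overlap < 0L || overlap >= frame_length) {
    stop("overlap must satisfy 0 <= overlap < frame_length", call. = FALSE)
  }
  x <- recording$samples
  n <- length(x) - offset
  if (n < frame_length) {
    stop("recording '", recording$recording_id, "' is shorter (", n,
         " usable samples) than one frame (", frame_length, ")",
         call. = FALSE)
  }
  step <- frame_length - overlap
  n_frames <- (n - frame_length) %/% step + 1L
  lapply(seq_len(n_frames) - 1L, function(i) {
    start <- offset + i * step
    list(samples = x[(start + 1L):(start + frame_length)],
         label = recording$label, source_id = recording$recording_id,
         frame_index = i)
  })
}

#' Frame every recording in a list
#'
#' Convenience wrapper over [frame_signal()]; recordings shorter than one
#' frame are skipped with a warning.
#'
#' @inheritParams frame_signal
#' @param recordings List of [emg_recording()]s.
#' @return Flat list of frames.
#' @export
frame_recordings <- function(recordings, frame_length = 2048L, overlap = 0L,
                             offset = 0L) {
  out <- list()
  for (rec in recordings) {
    frames <- tryCatch(
      frame_signal(rec, frame_length, overlap, offset),
      error = function(e) {
        warning("skipping recording '", rec$recording_id, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    out <- c(out, frames)
  }
  out
}
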