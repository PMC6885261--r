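## Synthetic MUAP-train EMG simulator.
##
## A recording is the superposition of per-motor-unit MUAP trains plus white
## Gaussian noise, band-limited with a zero-phase 4th-order Butterworth
## filter. Each motor unit draws one MUAP template (amplitude, duration, phase
## count from the class profile) and fires as a renewal process with
## Gaussian-jittered inter-pulse intervals. The three default class profiles
## encode the textbook clinical contrast: myopathic units are short, small and
## polyphasic; neuropathic units are long and large with fewer active units.

#' MUAP shape parameters
#'
#' @param amplitude_mv Peak absolute amplitude in millivolts (> 0).
#' @param duration_ms Total waveform duration in milliseconds (> 0).
#' @param n_phases Number of phases, i.e. baseline crossings + 1 (1..8).
#' @return Object of class `muap_shape_params`.
#' @export
muap_shape_params <- function(amplitude_mv, duration_ms, n_phases) {
  if (!is.numeric(amplitude_mv) || amplitude_mv <= 0) {
    stop("amplitude_mv must be > 0", call. = FALSE)
  }
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be > 0", call. = FALSE)
  }
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L || n_phases > 8L) {
    stop("n_phases must be in 1..8", call. = FALSE)
  }
  structure(list(amplitude_mv = amplitude_mv, duration_ms = duration_ms,
                 n_phases = n_phases), class = "muap_shape_params")
}

#' Class profile for the simulator
#'
#' Describes the MUAP morphology and firing statistics of one diagnostic
#' class. Normal distributions for amplitude and duration are truncated at 0
#' when sampled.
#'
#' @param class_label One of `emg_classes()`.
#' @param amplitude_dist `c(mean, sd)` of MUAP amplitude (mV).
#' @param duration_dist `c(mean, sd)` of MUAP duration (ms).
#' @param phases_dist Named numeric vector of probabilities over phase counts,
#'   e.g. `c("2" = .4, "3" = .4, "4" = .2)`.
#' @param n_motor_units Number of active motor units (>= 1).
#' @param firing_rate_hz Mean firing rate per unit (> 0).
#' @param firing_jitter Coefficient of variation of inter-pulse intervals, in
#'   `[0, 1)`.
#' @param noise_sd_mv Additive white-noise standard deviation (>= 0).
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(class_label, amplitude_dist, duration_dist,
                          phases_dist, n_motor_units, firing_rate_hz,
                          firing_jitter = 0.2, noise_sd_mv = 0.01) {
  class_label <- match.arg(class_label, EMG_CLASSES)
  stopifnot(length(amplitude_dist) == 2L, amplitude_dist[1] > 0,
            amplitude_dist[2] >= 0, length(duration_dist) == 2L,
            duration_dist[1] > 0, duration_dist[2] >= 0)
  if (is.null(names(phases_dist)) || any(phases_dist < 0) ||
      sum(phases_dist) <= 0) {
    stop("phases_dist must be a named nonnegative vector of probabilities",
         call. = FALSE)
  }
  n_motor_units <- as.integer(n_motor_units)
  if (n_motor_units < 1L) stop("n_motor_units must be >= 1", call. = FALSE)
  if (firing_rate_hz <= 0) stop("firing_rate_hz must be > 0", call. = FALSE)
  if (firing_jitter < 0 || firing_jitter >= 1) {
    stop("firing_jitter must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd_mv < 0) stop("noise_sd_mv must be >= 0", call. = FALSE)
  structure(list(class_label = class_label,
                 amplitude_dist = unname(amplitude_dist),
                 duration_dist = unname(duration_dist),
                 phases_dist = phases_dist / sum(phases_dist),
                 n_motor_units = n_motor_units,
                 firing_rate_hz = firing_rate_hz,
                 firing_jitter = firing_jitter,
                 noise_sd_mv = noise_sd_mv),
            class = "class_profile")
}

#' Default class profiles
#'
#' Simulator defaults encoding the classical electrodiagnostic contrast:
#' Normal 1.0 +/- 0.3 mV, 9 +/- 2 ms, 2-4 phases, 12 units; Myopathy
#' 0.4 +/- 0.15 mV, 5 +/- 1.5 ms, 4-6 phases, 12 units; Neuropathy
#' 1.6 +/- 0.5 mV, 14 +/- 3 ms, 2-4 phases, 5 units.
#'
#' @return Named list of three [class_profile()] objects.
#' @export
default_class_profiles <- function() {
  list(
    Normal = class_profile("Normal", c(1.0, 0.3), c(9, 2),
                           c("2" = .4, "3" = .4, "4" = .2),
                           n_motor_units = 12L, firing_rate_hz = 10),
    Myopathy = class_profile("Myopathy", c(0.4, 0.15), c(5, 1.5),
                             c("4" = .4, "5" = .4, "6" = .2),
                             n_motor_units = 12L, firing_rate_hz = 12),
    Neuropathy = class_profile("Neuropathy", c(1.6, 0.5), c(14, 3),
                               c("2" = .4, "3" = .4, "4" = .2),
                               n_motor_units = 5L, firing_rate_hz = 8)
  )
}

#' Acquisition configuration for the simulator
#'
#' Defaults mirror a standard clinical needle-EMG acquisition: 20 kHz sampling
#' for 5 s, band 5 Hz - 10 kHz. When the upper band edge reaches the Nyquist
#' frequency (as it does at the defaults) only the high-pass at the lower edge
#' is applied: discrete samples carry no content above Nyquist.
#'
#' @param sampling_rate_hz Sampling rate (default 20000).
#' @param duration_s Recording length in seconds (default 5).
#' @param bandpass_hz `c(low, high)` band edges in Hz (default `c(5, 10000)`).
#' @param seed Integer RNG seed.
#' @param quantize_bits Optional ADC resolution (e.g. 12); `NULL` (default)
#'   keeps continuous amplitudes.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate_hz = 20000, duration_s = 5,
                              bandpass_hz = c(5, 10000), seed = 1L,
                              quantize_bits = NULL) {
  stopifnot(sampling_rate_hz > 0, duration_s > 0, length(bandpass_hz) == 2L)
  if (!(bandpass_hz[1] > 0 && bandpass_hz[1] < bandpass_hz[2] &&
        bandpass_hz[2] <= sampling_rate_hz / 2)) {
    stop("band edges must satisfy 0 < low < high <= sampling_rate/2",
         call. = FALSE)
  }
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 bandpass_hz = bandpass_hz, seed = as.integer(seed),
                 quantize_bits = quantize_bits),
            class = "simulation_config")
}

#' Build a MUAP waveform template
#'
#' The waveform is a train of `n_phases` alternating-sign Gaussian lobes
#' spanning `duration_ms`, rescaled so the peak absolute value equals
#' `amplitude_mv`. For polyphasic templates (`n_phases >= 2`) the end lobes of
#' odd-phase templates are halved so the alternating lobe areas cancel and the
#' waveform returns to baseline with (near-)zero net area; a monophasic
#' template is a single lobe and necessarily carries net area.
#'
#' @param shape A [muap_shape_params()] (or its three fields as arguments via
#'   `muap_shape_params()`).
#' @param sampling_rate_hz Sampling rate used to discretize the template.
#' @return Numeric waveform of length `round(duration_ms * fs / 1000)` with
#'   exactly `n_phases - 1` sign changes.
#' @export
make_muap_template <- function(shape, sampling_rate_hz) {
  stopifnot(inherits(shape, "muap_shape_params"), sampling_rate_hz > 0)
  n <- round(shape$duration_ms * sampling_rate_hz / 1000)
  if (n < 4) {
    stop("duration_ms spans fewer than 4 samples at ", sampling_rate_hz,
         " Hz", call. = FALSE)
  }
  P <- shape$n_phases
  t <- (seq_len(n) - 0.5) / n           # in (0, 1)
  centers <- (seq_len(P) - 0.5) / P
  sigma <- 1 / (4 * P)                  # lobe width: tails die between lobes
  amps <- rep(1, P)
  if (P >= 3L && P %% 2L == 1L) amps[c(1L, P)] <- 0.5  # odd count: area cancels
  w <- numeric(n)
  for (p in seq_len(P)) {
    w <- w + (-1)^(p + 1) * amps[p] * exp(-(t - centers[p])^2 / (2 * sigma^2))
  }
  w * (shape$amplitude_mv / max(abs(w)))
}

# Truncated-at-zero normal draw (rejection; mean > 0 so acceptance is fast).
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

# Zero-phase 4th-order Butterworth band-limiting; high-pass only when the
# upper edge sits at (or numerically at) Nyquist.
bandlimit <- function(x, fs, band) {
  nyq <- fs / 2
  lo <- band[1] / nyq
  if (band[2] >= 0.99 * nyq) {
    bf <- signal::butter(4, lo, type = "high")
  } else {
    bf <- signal::butter(4, c(lo, band[2] / nyq), type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Simulate one labelled EMG recording
#'
#' Superimposes the MUAP trains of `profile$n_motor_units` motor units, adds
#' white Gaussian noise, and band-limits per the configuration. Deterministic
#' for a fixed `config$seed`.
#'
#' @param profile A [class_profile()].
#' @param config A [simulation_config()].
#' @param recording_id Identifier stored in the recording (default derived
#'   from the label and seed).
#' @return An [emg_recording()].
#' @export
simulate_recording <- function(profile, config = simulation_config(),
                               recording_id = NULL) {
  stopifnot(inherits(profile, "class_profile"),
            inherits(config, "simulation_config"))
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  x <- numeric(n)
  phase_vals <- as.integer(names(profile$phases_dist))
  for (u in seq_len(profile$n_motor_units)) {
    shape <- muap_shape_params(
      amplitude_mv = rnorm_pos(1, profile$amplitude_dist[1],
                               profile$amplitude_dist[2]),
      duration_ms = max(rnorm_pos(1, profile$duration_dist[1],
                                  profile$duration_dist[2]),
                        5000 / fs),    # keep >= 5 samples
      n_phases = phase_vals[sample.int(length(phase_vals), 1L,
                                       prob = profile$phases_dist)])
    tmpl <- make_muap_template(shape, fs)
    # renewal firing: jittered inter-pulse intervals, truncated positive
    mean_ipi <- 1 / profile$firing_rate_hz
    t_fire <- runif(1, 0, mean_ipi)    # random initial phase
    while (t_fire < config$duration_s) {
      i0 <- round(t_fire * fs) + 1L
      i1 <- min(i0 + length(tmpl) - 1L, n)
      if (i0 <= n) x[i0:i1] <- x[i0:i1] + tmpl[seq_len(i1 - i0 + 1L)]
      ipi <- rnorm_pos(1, mean_ipi, profile$firing_jitter * mean_ipi)
      t_fire <- t_fire + ipi
    }
  }
  if (profile$noise_sd_mv > 0) x <- x + rnorm(n, 0, profile$noise_sd_mv)
  x <- bandlimit(x, fs, config$bandpass_hz)
  if (!is.null(config$quantize_bits)) {
    levels <- 2^config$quantize_bits
    rng <- max(abs(x))
    if (rng > 0) x <- round(x / rng * (levels / 2 - 1)) / (levels / 2 - 1) * rng
  }
  if (is.null(recording_id)) {
    recording_id <- sprintf("%s_seed%d", profile$class_label, config$seed)
  }
  emg_recording(x, fs, label = profile$class_label,
                recording_id = recording_id, seed = config$seed)
}

#' Simulate a labelled multi-class dataset
#'
#' Generates `n_recordings_per_class` recordings for each profile, with
#' per-recording seeds drawn deterministically from `config$seed`.
#'
#' @param profiles List of [class_profile()]s with distinct labels (default
#'   [default_class_profiles()]).
#' @param n_recordings_per_class Recordings per class (>= 1).
#' @param config A [simulation_config()]; its `seed` drives the whole dataset.
#' @return List of [emg_recording()]s (classes interleaved per replicate).
#' @export
simulate_dataset <- function(profiles = default_class_profiles(),
                             n_recordings_per_class = 17L,
                             config = simulation_config()) {
  labels <- vapply(profiles, `[[`, character(1), "class_label")
  if (anyDuplicated(labels)) {
    stop("duplicate class labels in profiles: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  n_recordings_per_class <- as.integer(n_recordings_per_class)
  if (n_recordings_per_class < 1L) {
    stop("n_recordings_per_class must be >= 1", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_total <- length(profiles) * n_recordings_per_class
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  out <- vector("list", n_total)
  k <- 0L
  for (r in seq_len(n_recordings_per_class)) {
    for (p in seq_along(profiles)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- rec_seeds[k]
      out[[k]] <- simulate_recording(
        profiles[[p]], cfg,
        recording_id = sprintf("%s_%03d", labels[p], r))
    }
  }
  out
}

# Save/restore the global RNG state so seeded simulators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
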