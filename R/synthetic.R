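# Synthetic two-class motor-imagery EEG with known ground truth.
#
# Band-limited sources (white noise bandpassed to the mu/alpha range and
# normalized to unit RMS) are mixed through random orthonormal columns into C
# sensors; the first source carries the class effect: its amplitude is
# sqrt(erd_ratio) times larger in class 1 than in class 2 (a stationary
# within-trial ERD/ERS power modulation).  Spatially white Gaussian sensor
# noise is added, plus optional sparse single-channel half-cosine artifact
# bursts mimicking EMG/electrode transients.

#' Synthetic motor-imagery EEG configuration
#'
#' @param n_trials_per_class trials per class. Default 60.
#' @param n_channels sensors C. Default 16.
#' @param fs sampling rate in Hz. Default 250.
#' @param duration epoch length in seconds. Default 3.
#' @param n_sources number of band-limited sources (<= C). Default 4.
#' @param source_band source rhythm band in Hz. Default c(9, 13).
#' @param erd_ratio class-1 / class-2 power ratio of the discriminative
#'   source (> 0, != 1 for a learnable problem). Default 3.
#' @param noise_sigma sensor-noise standard deviation relative to the
#'   unit-RMS sources. Default 1.
#' @param artifact_rate fraction of trials carrying an artifact burst.
#'   Default 0.
#' @param artifact_amp burst peak as a multiple of the trial's background
#'   RMS. Default 20.
#' @param artifact_width burst width in seconds. Default 0.1.
#' @param seed integer seed. Default 1.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_trials_per_class = 60L, n_channels = 16L, fs = 250,
                         duration = 3, n_sources = 4L, source_band = c(9, 13),
                         erd_ratio = 3, noise_sigma = 1, artifact_rate = 0,
                         artifact_amp = 20, artifact_width = 0.1, seed = 1L) {
  if (!is_count(n_trials_per_class) || n_trials_per_class < 2L)
    abort_validation("need at least 2 trials per class")
  if (!is_count(n_channels) || n_channels < 2L)
    abort_validation("need at least 2 channels")
  if (!is_count(n_sources) || n_sources < 1L || n_sources > n_channels)
    abort_validation("need 1 <= n_sources <= n_channels")
  if (erd_ratio <= 0 || erd_ratio == 1)
    abort_validation("`erd_ratio` must be positive and != 1")
  if (artifact_rate < 0 || artifact_rate > 1)
    abort_validation("`artifact_rate` must lie in [0, 1]")
  if (fs <= 0 || duration <= 0) abort_validation("fs and duration must be > 0")
  if (source_band[2] >= fs / 2)
    abort_validation("source band must lie below Nyquist")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, n_sources = as.integer(n_sources),
                 source_band = source_band, erd_ratio = erd_ratio,
                 noise_sigma = noise_sigma, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp, artifact_width = artifact_width,
                 seed = as.integer(seed)),
            class = "synth_config")
}

unit_rms <- function(x) x / sqrt(mean(x^2))

#' Generate synthetic two-class motor-imagery EEG
#'
#' @param config a [synth_config()].
#' @return a list: `epochs` (an [eeg_epochs]; trials interleaved class
#'   1, 2, 1, 2, ...) and `truth` (mixing matrix, discriminative source
#'   index, artifact trial indices, per-trial source amplitude scalars).
#' @examples
#' sim <- generate_mi_eeg(synth_config(n_trials_per_class = 5, n_channels = 4,
#'                                     fs = 100, duration = 1, seed = 7))
#' dim(sim$epochs$data)
#' @export
generate_mi_eeg <- function(config = synth_config()) {
  if (!inherits(config, "synth_config"))
    abort_validation("`config` must come from synth_config()")
  cfg <- config
  Tn <- round(cfg$fs * cfg$duration)
  nt <- 2L * cfg$n_trials_per_class
  flt <- signal::butter(4, cfg$source_band / (cfg$fs / 2), type = "pass")
  pad <- round(cfg$fs)           # settle the filter outside the kept window
  with_seed(cfg$seed, {
    mixing <- qr.Q(qr(matrix(stats::rnorm(cfg$n_channels * cfg$n_sources),
                             cfg$n_channels)))[, seq_len(cfg$n_sources),
                                               drop = FALSE]
    labels <- rep(c(1L, 2L), cfg$n_trials_per_class)
    dat <- array(NA_real_, c(nt, cfg$n_channels, Tn))
    amp <- numeric(nt)
    for (i in seq_len(nt)) {
      S <- matrix(NA_real_, cfg$n_sources, Tn)
      for (s in seq_len(cfg$n_sources)) {
        raw <- as.numeric(signal::filtfilt(flt, stats::rnorm(Tn + 2 * pad)))
        S[s, ] <- unit_rms(raw[(pad + 1):(pad + Tn)])
      }
      amp[i] <- if (labels[i] == 1L) sqrt(cfg$erd_ratio) else 1
      S[1, ] <- S[1, ] * amp[i]
      dat[i, , ] <- mixing %*% S +
        cfg$noise_sigma * matrix(stats::rnorm(cfg$n_channels * Tn),
                                 cfg$n_channels)
    }
    epochs <- eeg_epochs(dat, cfg$fs, labels, t_start = 0)
    artifact_trials <- integer(0)
    if (cfg$artifact_rate > 0) {
      inj <- inject_artifacts(epochs, cfg$artifact_rate, cfg$artifact_amp,
                              cfg$artifact_width,
                              seed = cfg$seed + 7919L)
      epochs <- inj$epochs
      artifact_trials <- inj$trials
    }
    list(epochs = epochs,
         truth = list(mixing = mixing, discriminative_source_index = 1L,
                      artifact_trials = artifact_trials,
                      source_amplitude = amp, config = cfg))
  })
}

#' Inject transient single-channel artifact bursts
#'
#' Adds a half-cosine burst (peak `amp` times the trial's background RMS,
#' width `width` seconds) to one random channel at a random time in
#' `round(rate * n_trials)` distinct trials.  Labels are untouched;
#' unaffected trials are bit-identical.
#'
#' @param x an [eeg_epochs] object.
#' @param rate fraction of trials to affect, in `[0, 1]`.
#' @param amp burst peak in background-RMS units. Default 20.
#' @param width burst width in seconds. Default 0.1.
#' @param seed integer seed.
#' @return list: `epochs` (modified copy), `trials` (sorted affected indices).
#' @export
inject_artifacts <- function(x, rate, amp = 20, width = 0.1, seed = 1L) {
  if (rate < 0 || rate > 1) abort_validation("`rate` must lie in [0, 1]")
  Tn <- n_samples(x)
  wn <- round(width * x$fs)
  if (wn >= Tn) abort_validation("artifact width exceeds epoch duration")
  wn <- max(wn, 3L)
  n_aff <- round(rate * n_trials(x))
  if (n_aff == 0L)
    return(list(epochs = x, trials = integer(0)))
  with_seed(seed, {
    trials <- sort(sample(n_trials(x), n_aff))
    dat <- x$data
    for (i in trials) {
      ch <- sample(n_channels(x), 1L)
      start <- sample(Tn - wn + 1L, 1L)
      rms <- sqrt(mean(dat[i, , ]^2))
      t_rel <- seq_len(wn)
      burst <- amp * rms * cos(pi * (t_rel - (wn + 1) / 2) / wn)
      dat[i, ch, start:(start + wn - 1L)] <-
        dat[i, ch, start:(start + wn - 1L)] + burst
    }
    list(epochs = eeg_epochs(dat, x$fs, x$labels, x$channel_names, x$t_start),
         trials = trials)
  })
}

#' Named synthetic fixture presets
#'
#' `"clean-small"`: 120 trials, 16 channels, defaults, no artifacts.
#' `"artifact-10pct"`: same but 10% of trials carry a 20x-RMS burst.
#' `"highdim-59ch"`: 59 channels, 6 sources, 100 Hz.
#'
#' @param name preset name.
#' @param seed integer seed. Default 1.
#' @return a [synth_config()].
#' @export
fixture_preset <- function(name, seed = 1L) {
  presets <- list(
    "clean-small" = function(s) synth_config(seed = s),
    "artifact-10pct" = function(s) synth_config(artifact_rate = 0.1, seed = s),
    "highdim-59ch" = function(s) synth_config(n_channels = 59L, n_sources = 6L,
                                              fs = 100, seed = s))
  if (!name %in% names(presets))
    abort_validation(paste0("unknown preset '", name, "'; available: ",
                            paste(names(presets), collapse = ", ")))
  presets[[name]](seed)
}
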