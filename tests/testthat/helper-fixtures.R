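# Shared fixtures and oracles, all built in code.

# Small epoched container with a given per-trial signal builder.
make_epochs <- function(n_trials = 4, n_channels = 2, n_samp = 100, fs = 100,
                        labels = rep(c(1, 2), length.out = n_trials),
                        fill = function(i, c) rnorm(n_samp)) {
  dat <- array(0, c(n_trials, n_channels, n_samp))
  for (i in seq_len(n_trials)) for (c in seq_len(n_channels))
    dat[i, c, ] <- fill(i, c)
  eeg_epochs(dat, fs, labels)
}

sine_epochs <- function(freq, fs = 250, n_samp = fs * 2, n_trials = 2,
                        n_channels = 2) {
  t <- seq_len(n_samp) / fs
  make_epochs(n_trials, n_channels, n_samp, fs,
              fill = function(i, c) sin(2 * pi * freq * t))
}

# Digital transfer-function magnitude at frequency f (Hz): direct polynomial
# evaluation of b(z)/a(z) on the unit circle — independent of the filtering
# code path.
tf_mag <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

signal_power <- function(x) mean(x^2)

# Brute-force smoothness penalty: ordered-pair double sum over the adjacency.
brute_penalty <- function(z, A) {
  sum(outer(z, z, function(a, b) (a - b)^2) * A)
}

# Tiny synthetic set used across spatial-filter tests.
tiny_sim <- function(seed = 1, ...) {
  generate_mi_eeg(synth_config(n_trials_per_class = 15, n_channels = 6,
                               fs = 100, duration = 1, seed = seed, ...))
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
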