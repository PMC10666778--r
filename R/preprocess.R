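#' Butterworth band specification
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low < high`.
#' @param order Butterworth order (>= 1); the broadband preprocessing default
#'   in this package is a 4th-order 8-32 Hz filter.
#' @return a `band_spec` list.
#' @export
band_spec <- function(low_hz, high_hz, order = 4L) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      !(low_hz > 0 && high_hz > low_hz))
    abort_validation("need 0 < low_hz < high_hz")
  if (!is_count(order) || order < 1L)
    abort_validation("`order` must be an integer >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' Default filter-bank bands
#'
#' Three overlapping bands (4-20, 8-24, 12-28 Hz) jointly covering the mu,
#' alpha and beta rhythms, each realized as a 4th-order Butterworth bandpass.
#' @return list of three [band_spec] objects.
#' @export
default_bands <- function() {
  list(band_spec(4, 20), band_spec(8, 24), band_spec(12, 28))
}

#' Bandpass-filter epoched EEG
#'
#' Applies a Butterworth bandpass per trial and channel.  By default the
#' filter is run forward and backward (`zero_phase = TRUE`), which cancels
#' group delay — appropriate for offline epoched analysis where shifting
#' ERD/ERS timing would be harmful — at the cost of doubling the effective
#' order.
#'
#' @param x an [eeg_epochs] object.
#' @param band a [band_spec].
#' @param zero_phase forward-backward filtering? Default `TRUE`.
#' @return filtered [eeg_epochs], same shape and labels.
#' @export
bandpass <- function(x, band, zero_phase = TRUE) {
  if (!inherits(band, "band_spec")) abort_validation("`band` must be band_spec")
  nyq <- x$fs / 2
  if (band$high_hz >= nyq)
    abort_validation(sprintf("band edge %g Hz >= Nyquist (%g Hz)",
                             band$high_hz, nyq))
  flt <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                        type = "pass")
  apply_filter(x, flt, zero_phase)
}

#' Notch-filter epoched EEG
#'
#' Second-order IIR notch (constrained pole-zero biquad) for power-line
#' rejection.
#'
#' @param x an [eeg_epochs] object.
#' @param freq_hz notch center frequency in Hz (e.g. 50).
#' @param q quality factor; bandwidth is `freq_hz / q`. Default 30.
#' @param zero_phase forward-backward filtering? Default `TRUE`.
#' @return filtered [eeg_epochs].
#' @export
notch <- function(x, freq_hz, q = 30, zero_phase = TRUE) {
  nyq <- x$fs / 2
  if (!is.numeric(freq_hz) || length(freq_hz) != 1L ||
      freq_hz <= 0 || freq_hz >= nyq)
    abort_validation(sprintf("notch frequency must lie in (0, %g) Hz", nyq))
  w0 <- pi * freq_hz / nyq
  bw <- w0 / q
  r <- 1 - tan(bw / 2) / (1 + tan(bw / 2))   # pole radius from -3 dB bandwidth
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * (1 + a[2] + a[3]) / (1 + b[2] + b[3])  # unit gain at DC
  apply_filter(x, list(b = b, a = a), zero_phase)
}

apply_filter <- function(x, flt, zero_phase) {
  d <- dim(x$data)
  out <- x$data
  filt <- as.vector(flt$b)
  den <- as.vector(flt$a)
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      s <- x$data[i, c, ]
      out[i, c, ] <- if (zero_phase)
        as.numeric(signal::filtfilt(filt, den, s))
      else as.numeric(signal::filter(filt, den, s))
    }
  }
  eeg_epochs(out, x$fs, x$labels, x$channel_names, x$t_start)
}

#' Crop epochs to a time window
#'
#' Keeps the half-open window `[t0, t1)` (seconds relative to cue onset,
#' 0-based sample indexing), so the result has `round((t1 - t0) * fs)`
#' samples.
#'
#' @param x an [eeg_epochs] object.
#' @param t0,t1 window bounds in seconds, `t_start <= t0 < t1 <=` epoch end.
#' @return cropped [eeg_epochs] with updated `t_start`.
#' @export
crop <- function(x, t0, t1) {
  d <- dim(x$data)
  t_end <- x$t_start + d[3] / x$fs
  eps <- 1e-9
  if (!(t0 >= x$t_start - eps && t1 <= t_end + eps && t0 < t1))
    abort_validation(sprintf(
      "window [%g, %g] invalid for epoch [%g, %g]", t0, t1, x$t_start, t_end))
  i0 <- round((t0 - x$t_start) * x$fs)
  n <- round((t1 - t0) * x$fs)
  if (n < 2L) abort_validation("cropped window shorter than 2 samples")
  if (i0 + n > d[3]) abort_validation("window extends past epoch end")
  eeg_epochs(x$data[, , (i0 + 1):(i0 + n), drop = FALSE], x$fs, x$labels,
             x$channel_names, t_start = x$t_start + i0 / x$fs)
}

#' Stratified 64/16/20 train/validation/test split
#'
#' The test set is fold `fold` of a class-stratified 5-fold partition (20% of
#' trials); the remaining 80% is stratified-split 80/20 into training (64%)
#' and validation (16%).  Deterministic for a fixed seed.
#'
#' @param x an [eeg_epochs] object (only labels are used).
#' @param fold which fold's test set, `1..n_folds`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return a `split_plan` list with `train_idx`, `val_idx`, `test_idx`,
#'   `fold_id`, `seed`.
#' @export
split_64_16_20 <- function(x, fold, n_folds = 5L, seed = 1L) {
  labels <- x$labels
  if (!is_count(fold) || fold < 1L || fold > n_folds)
    abort_validation(sprintf("`fold` must be in 1..%d", n_folds))
  counts <- table(labels)
  if (length(counts) < 2L || any(counts < n_folds))
    abort_validation("each class needs at least n_folds trials")
  assign_folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in as.integer(names(counts))) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  test_idx <- which(assign_folds == fold)
  rest <- which(assign_folds != fold)
  val_idx <- with_seed(seed + 1000L * fold, {
    out <- integer(0)
    for (cl in as.integer(names(counts))) {
      idx <- sample(rest[labels[rest] == cl])
      n_val <- round(0.2 * length(idx))
      out <- c(out, idx[seq_len(max(n_val, 1L))])
    }
    sort(out)
  })
  train_idx <- setdiff(rest, val_idx)
  for (part in list(train_idx, val_idx, test_idx))
    if (length(unique(labels[part])) < 2L)
      abort_validation("a class is absent from one split part")
  structure(list(train_idx = sort(train_idx), val_idx = sort(val_idx),
                 test_idx = sort(test_idx), fold_id = as.integer(fold),
                 seed = as.integer(seed)),
            class = "split_plan")
}
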