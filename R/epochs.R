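#' Epoched multichannel EEG container
#'
#' Bundles a trials x channels x samples array of epoched EEG (microvolts)
#' with its sampling rate, per-trial class labels and channel names.  All
#' fitting, preprocessing and evaluation functions in the package consume and
#' return this container.
#'
#' @param data numeric 3-d array, `n_trials x n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels integer vector of per-trial class tags, values in `{1, 2}`.
#' @param channel_names character vector of unique channel names; defaults to
#'   `"ch1" ... "chC"`.
#' @param t_start time of the first sample in seconds relative to cue onset.
#'
#' @return An object of class `"eeg_epochs"`: a list with elements `data`,
#'   `fs`, `labels`, `channel_names`, `t_start`.
#'
#' @examples
#' x <- eeg_epochs(array(rnorm(4 * 3 * 100), c(4, 3, 100)), fs = 100,
#'                 labels = c(1, 1, 2, 2))
#' x
#' @export
eeg_epochs <- function(data, fs, labels, channel_names = NULL, t_start = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_validation("`data` must be a 3-d array [trials x channels x samples]")
  storage.mode(data) <- "double"
  d <- dim(data)
  if (d[1] < 1L) abort_validation("container must hold at least one trial")
  if (d[3] < 2L) abort_validation("epochs need at least 2 samples")
  if (any(!is.finite(data)))
    abort_validation("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    abort_validation("`fs` must be a positive scalar (Hz)")
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    abort_validation(sprintf("length(labels) == %d but n_trials == %d",
                             length(labels), d[1]))
  bad <- which(!(labels %in% c(1L, 2L)))
  if (length(bad))
    abort_validation(paste0("labels must be in {1, 2}; offending trials: ",
                            paste(utils::head(bad, 10L), collapse = ", ")))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[2])
    abort_validation("channel_names length must equal n_channels")
  if (anyDuplicated(channel_names))
    abort_validation("channel_names must be unique")
  if (!is.numeric(t_start) || length(t_start) != 1L || !is.finite(t_start))
    abort_validation("`t_start` must be a finite scalar (seconds)")
  structure(
    list(data = data, fs = as.numeric(fs), labels = labels,
         channel_names = channel_names, t_start = as.numeric(t_start)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window: [%.3f, %.3f] s; classes: %d / %d trials\n",
              x$t_start, x$t_start + d[3] / x$fs,
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Number of trials, channels and samples
#' @param x an `eeg_epochs` object.
#' @return integer scalar.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Select trials from an epoch container
#'
#' @param x an `eeg_epochs` object.
#' @param trials integer index vector of trials to keep.
#' @return an `eeg_epochs` with the selected trials (order preserved).
#' @export
select_trials <- function(x, trials) {
  trials <- as.integer(trials)
  if (length(trials) == 0L) abort_validation("no trials selected")
  if (any(trials < 1L | trials > n_trials(x)))
    abort_validation("trial index out of range")
  eeg_epochs(x$data[trials, , , drop = FALSE], x$fs, x$labels[trials],
             x$channel_names, x$t_start)
}

# Single trial as a C x T matrix.
trial_matrix <- function(x, i) {
  matrix(x$data[i, , ], nrow = dim(x$data)[2])
}

check_two_classes <- function(x) {
  if (length(unique(x$labels)) < 2L)
    abort_validation("both classes must be present for fitting")
  invisible(x)
}
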