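# Epoch container I/O: a native binary dialect and EDF + event-table reading.
#
# Native format ("eegbin"): 8-byte magic "EEGEPOCH", a 4-byte little-endian
# unsigned header length, a JSON header with dims/fs/labels/channel_names/
# t_start, then the data tensor as little-endian float64 in R column-major
# order (trials fastest).  Bit-exact round trips by construction.

NATIVE_MAGIC <- charToRaw("EEGEPOCH")

#' Write epoched EEG to the native container
#'
#' @param x an [eeg_epochs] object.
#' @param path output file path.
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(x, path, overwrite = FALSE) {
  if (!inherits(x, "eeg_epochs")) abort_validation("`x` must be eeg_epochs")
  if (n_trials(x) < 1L) abort_validation("refusing to write a 0-trial container")
  if (file.exists(path) && !isTRUE(overwrite))
    abort_io(sprintf("'%s' exists; pass overwrite = TRUE to replace it", path))
  header <- jsonlite::toJSON(list(
    version = 1L, dims = dim(x$data), fs = x$fs, labels = x$labels,
    channel_names = x$channel_names, t_start = x$t_start,
    dtype = "float64-le"), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort_io(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeBin(NATIVE_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(x$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read epoched EEG from disk
#'
#' Two dialects are supported: the package's native container (written by
#' [write_epochs()]) and EDF (European Data Format) continuous recordings
#' accompanied by a sidecar event table.  The event table is a CSV with
#' columns `onset_sample` (0-based sample of the epoch start), `n_samples`
#' (epoch length, identical across rows) and `label` (1 or 2); the continuous
#' recording is sliced into equal-length epochs accordingly.
#'
#' @param path file path (`.edf` file for the EDF dialect).
#' @param dialect `"native"` or `"edf"`.
#' @param events path to the event CSV (EDF dialect only); defaults to
#'   `path` with its extension replaced by `.events.csv`.
#' @param t_start epoch start time in seconds relative to cue onset for the
#'   EDF dialect (the native container stores its own).
#' @return an [eeg_epochs] object.
#' @export
read_epochs <- function(path, dialect = c("native", "edf"), events = NULL,
                        t_start = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("file not found: '%s'", path))
  if (dialect == "native") read_epochs_native(path)
  else read_epochs_edf(path, events, t_start)
}

read_epochs_native <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) != 8L || !identical(magic, NATIVE_MAGIC))
    abort_io(sprintf("'%s' is not a native epoch container", path))
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  dims <- as.integer(header$dims)
  n <- prod(dims)
  dat <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(dat) != n) abort_io(sprintf("'%s' is truncated", path))
  eeg_epochs(array(dat, dims), header$fs, header$labels,
             header$channel_names, header$t_start)
}

read_epochs_edf <- function(path, events, t_start) {
  if (is.null(events)) events <- sub("\\.edf$", ".events.csv", path,
                                     ignore.case = TRUE)
  if (!file.exists(events))
    abort_io(sprintf("event table not found: '%s'", events))
  ev <- utils::read.csv(events)
  need <- c("onset_sample", "n_samples", "label")
  if (!all(need %in% names(ev)))
    abort_validation(paste("event table must have columns:",
                           paste(need, collapse = ", ")))
  if (nrow(ev) == 0L) abort_validation("event table is empty")
  if (length(unique(ev$n_samples)) != 1L)
    abort_validation("unequal epoch lengths in event table")
  bad <- which(!(ev$label %in% c(1, 2)))
  if (length(bad))
    abort_validation(paste0("labels must be in {1, 2}; offending trials: ",
                            paste(bad, collapse = ", ")))
  rec <- read_edf(path)
  len <- ev$n_samples[1]
  nt <- nrow(ev)
  dat <- array(NA_real_, c(nt, nrow(rec$signals), len))
  for (i in seq_len(nt)) {
    a <- ev$onset_sample[i] + 1L           # event table is 0-based
    b <- a + len - 1L
    if (a < 1L || b > ncol(rec$signals))
      abort_validation(sprintf("epoch %d ([%d, %d]) outside recording", i, a, b))
    dat[i, , ] <- rec$signals[, a:b]
  }
  eeg_epochs(dat, rec$fs, ev$label, rec$channel_names, t_start)
}

# Minimal EDF parser (continuous recording, equal sampling rate across
# signals).  EDF: 256-byte ASCII main header, 256 bytes of per-signal header
# fields, then data records of 16-bit little-endian integers which are mapped
# to physical units linearly from the digital/physical min/max fields.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") != 256L)
    abort_io(sprintf("'%s' is not an EDF file (short header)", path))
  field <- function(s, a, b) trimws(substr(s, a, b))
  n_records <- as.integer(field(hdr, 237, 244))
  record_dur <- as.numeric(field(hdr, 245, 252))
  ns <- as.integer(field(hdr, 253, 256))
  if (is.na(ns) || ns < 1L) abort_io(sprintf("'%s': bad EDF signal count", path))
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  take <- function(width, offset) {
    # per-signal fields are stored field-major: all labels, all transducers...
    vapply(seq_len(ns), function(i) {
      a <- offset + (i - 1L) * width + 1L
      trimws(substr(sig_hdr, a, a + width - 1L))
    }, character(1))
  }
  labels     <- take(16L, 0L)
  phys_min   <- as.numeric(take(8L, ns * (16 + 80 + 8)))
  phys_max   <- as.numeric(take(8L, ns * (16 + 80 + 8 + 8)))
  dig_min    <- as.numeric(take(8L, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max    <- as.numeric(take(8L, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  spr        <- as.integer(take(8L, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  if (length(unique(spr)) != 1L)
    abort_validation("EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- matrix(NA_real_, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw16 <- readBin(con, "integer", n = spr[s], size = 2L,
                       endian = "little", signed = TRUE)
      if (length(raw16) != spr[s]) abort_io(sprintf("'%s' is truncated", path))
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      signals[s, cols] <- (raw16 - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  list(signals = signals, fs = fs, channel_names = make.unique(labels))
}

# Minimal EDF writer used for round-trip testing and for exporting synthetic
# recordings.  Quantizes to 16 bits over the per-channel range.
write_edf <- function(signals, fs, path, channel_names = NULL) {
  ns <- nrow(signals)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ns))
  spr <- as.integer(fs)                  # one-second records
  n_records <- ncol(signals) %/% spr
  if (n_records * spr != ncol(signals))
    abort_validation("signal length must be a whole number of 1 s records")
  pad <- function(x, w) formatC(strtrim(as.character(x), w), width = w,
                                flag = "-")
  # physical range fields are 8 ASCII bytes; format first and re-parse so the
  # quantization gain matches what a reader will compute from the file
  fmt8 <- function(x) strtrim(formatC(x, format = "g", digits = 4), 8L)
  phys_min <- apply(signals, 1, min); phys_max <- apply(signals, 1, max)
  same <- phys_max - phys_min < .Machine$double.eps
  phys_max[same] <- phys_min[same] + 1
  pmin_s <- fmt8(phys_min); pmax_s <- fmt8(phys_max)
  phys_min <- as.numeric(pmin_s); phys_max <- as.numeric(pmax_s)
  phys_max[phys_max <= phys_min] <- phys_min[phys_max <= phys_min] + 1
  pmax_s <- fmt8(phys_max); phys_max <- as.numeric(pmax_s)
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_records, 8), pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  w <- function(x, width) writeChar(paste(pad(x, width), collapse = ""), con,
                                    eos = NULL, useBytes = TRUE)
  w(substr(channel_names, 1, 16), 16); w(rep("", ns), 80); w(rep("uV", ns), 8)
  w(pmin_s, 8); w(pmax_s, 8)
  w(dig_min, 8); w(dig_max, 8); w(rep("", ns), 80); w(rep(spr, ns), 8)
  w(rep("", ns), 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      cols <- ((r - 1L) * spr + 1L):(r * spr)
      dig <- round((signals[s, cols] - phys_min[s]) / gain[s] + dig_min[s])
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Export per-trial features as CSV
#'
#' Writes a table `trial_id, label, f_1 .. f_2K` for inspection or use in
#' external classifiers.
#'
#' @param features numeric matrix, trials x features.
#' @param labels per-trial labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_features <- function(features, labels, path) {
  df <- data.frame(trial_id = seq_len(nrow(features)), label = labels)
  colnames(features) <- paste0("f_", seq_len(ncol(features)))
  utils::write.csv(cbind(df, features), path, row.names = FALSE)
  invisible(path)
}
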