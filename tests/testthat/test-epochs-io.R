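test_that("container enforces its invariants", {
  dat <- array(rnorm(4 * 3 * 50), c(4, 3, 50))
  x <- eeg_epochs(dat, 100, c(1, 1, 2, 2))
  expect_s3_class(x, "eeg_epochs")
  expect_identical(dim(x), c(4L, 3L, 50L))
  expect_error(eeg_epochs(dat, 100, c(1, 1, 2)), "length\\(labels\\)")
  expect_error(eeg_epochs(dat, 100, c(1, 1, 2, 3)), "offending trials: 4")
  expect_error(eeg_epochs(dat, -1, c(1, 1, 2, 2)), "positive")
  expect_error(eeg_epochs(dat, 100, c(1, 1, 2, 2),
                          channel_names = c("a", "a", "b")), "unique")
  dat[1, 1, 1] <- NA
  expect_error(eeg_epochs(dat, 100, c(1, 1, 2, 2)), "non-finite")
})

test_that("native container round-trips bit-exactly", {
  x <- make_epochs(n_trials = 6, n_channels = 4, n_samp = 120,
                   labels = c(1, 2, 1, 2, 1, 2))
  path <- withr::local_tempfile(fileext = ".eegbin")
  write_epochs(x, path)
  y <- read_epochs(path, "native")
  expect_identical(y$data, x$data)
  expect_identical(y$labels, x$labels)
  expect_identical(y$fs, x$fs)
  expect_identical(y$channel_names, x$channel_names)
  expect_identical(y$t_start, x$t_start)
  # overwrite contract
  expect_error(write_epochs(x, path), "overwrite")
  expect_silent(write_epochs(x, path, overwrite = TRUE))
  expect_error(read_epochs(file.path(tempdir(), "nope.eegbin")), "not found")
})

test_that("0-trial container cannot be constructed or written", {
  expect_error(eeg_epochs(array(0, c(0, 2, 10)), 100, integer(0)))
})

test_that("EDF recordings slice into epochs via the event table", {
  fs <- 100
  n_sec <- 6
  t <- seq_len(fs * n_sec) / fs
  sig <- rbind(50 * sin(2 * pi * 5 * t), 30 * cos(2 * pi * 9 * t))
  edf <- withr::local_tempfile(fileext = ".edf")
  vpcsp:::write_edf(sig, fs, edf, channel_names = c("C3", "C4"))
  ev <- data.frame(onset_sample = c(0, 200, 400), n_samples = 150,
                   label = c(1, 2, 1))
  evp <- sub("\\.edf$", ".events.csv", edf)
  write.csv(ev, evp, row.names = FALSE)
  x <- read_epochs(edf, "edf")
  expect_identical(dim(x), c(3L, 2L, 150L))
  expect_identical(x$labels, c(1L, 2L, 1L))
  expect_identical(x$channel_names, c("C3", "C4"))
  expect_equal(x$fs, fs)
  # 16-bit quantization over the channel range: relative error small
  expect_lt(max(abs(x$data[1, 1, ] - sig[1, 1:150])), 50 * 2 / 32767 * 2)

  # empty event table -> validation error, no partial object
  write.csv(ev[0, ], evp, row.names = FALSE)
  expect_error(read_epochs(edf, "edf"), "empty")
  # out-of-range label
  ev$label[2] <- 3
  write.csv(ev, evp, row.names = FALSE)
  expect_error(read_epochs(edf, "edf"), "offending")
  # unequal epoch lengths
  ev$label[2] <- 2
  ev$n_samples <- c(150, 100, 150)
  write.csv(ev, evp, row.names = FALSE)
  expect_error(read_epochs(edf, "edf"), "unequal")
})

test_that("feature CSV export writes the labelled table", {
  f <- matrix(rnorm(12), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_features(f, c(1, 2, 1), path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("trial_id", "label", "f_1", "f_2", "f_3", "f_4"))
  expect_equal(as.matrix(tab[, 3:6]), f, ignore_attr = TRUE)
})
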