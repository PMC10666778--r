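test_that("bandpass attenuation matches the Butterworth magnitude oracle", {
  fs <- 250
  band <- band_spec(8, 32, 4)
  flt <- signal::butter(band$order, c(8, 32) / (fs / 2), type = "pass")
  keep <- (0.5 * fs):(1.5 * fs)        # discard 0.5 s edges

  # stopband: 50 Hz through the zero-phase filter loses >= 99% power
  x50 <- sine_epochs(50, fs)
  y50 <- bandpass(x50, band)
  ratio50 <- signal_power(y50$data[1, 1, keep]) / signal_power(x50$data[1, 1, keep])
  oracle50 <- tf_mag(flt$b, flt$a, 50, fs)^4   # forward-backward: |H|^4 power
  expect_lt(ratio50, 0.01)
  expect_equal(ratio50, oracle50, tolerance = 0.2)

  # passband: 15 Hz passes within 10%
  x15 <- sine_epochs(15, fs)
  y15 <- bandpass(x15, band)
  ratio15 <- signal_power(y15$data[1, 1, keep]) / signal_power(x15$data[1, 1, keep])
  oracle15 <- tf_mag(flt$b, flt$a, 15, fs)^4
  expect_gt(ratio15, 0.9)
  expect_lt(ratio15, 1.1)
  expect_equal(ratio15, oracle15, tolerance = 0.05)

  # all-zero input stays zero; band above Nyquist rejected
  xz <- make_epochs(2, 2, 200, fs, fill = function(i, c) rep(0, 200))
  expect_equal(bandpass(xz, band)$data, xz$data)
  expect_error(bandpass(x50, band_spec(8, 130)), "Nyquist")
})

test_that("bandpass is linear and preserves trials and labels", {
  fs <- 100
  set.seed(4)
  a <- make_epochs(3, 2, 150, fs)
  b <- make_epochs(3, 2, 150, fs)
  band <- band_spec(8, 30)
  combo <- a
  combo$data <- 2 * a$data - 3 * b$data
  lhs <- bandpass(combo, band)$data
  rhs <- 2 * bandpass(a, band)$data - 3 * bandpass(b, band)$data
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_identical(bandpass(a, band)$labels, a$labels)
  expect_identical(dim(bandpass(a, band)), dim(a))
})

test_that("notch rejects its center frequency and passes the rest", {
  fs <- 250
  keep <- (0.5 * fs):(1.5 * fs)
  x50 <- sine_epochs(50, fs)
  r50 <- signal_power(notch(x50, 50)$data[1, 1, keep]) /
    signal_power(x50$data[1, 1, keep])
  expect_lt(r50, 0.05)
  x10 <- sine_epochs(10, fs)
  r10 <- signal_power(notch(x10, 50)$data[1, 1, keep]) /
    signal_power(x10$data[1, 1, keep])
  expect_gt(r10, 0.95)
  expect_lt(r10, 1.05)
  xz <- make_epochs(1, 1, 500, fs, labels = 1, fill = function(i, c) rep(0, 500))
  expect_equal(notch(xz, 50)$data, xz$data)
  expect_error(notch(x10, 130), "notch frequency")
})

test_that("crop uses half-open sample windows", {
  x <- make_epochs(2, 2, 400, fs = 100)       # 4 s epoch at 100 Hz
  y <- crop(x, 0.5, 3.5)
  expect_identical(n_samples(y), 300L)
  expect_equal(y$t_start, 0.5)
  expect_equal(y$data[1, 1, 1], x$data[1, 1, 51])
  # full-epoch crop is the identity
  z <- crop(x, 0, 4)
  expect_identical(z$data, x$data)
  expect_error(crop(x, 1, 1), "invalid")
  expect_error(crop(x, -0.5, 2), "invalid")
})

test_that("64/16/20 split is sized, stratified, disjoint and reproducible", {
  x <- make_epochs(100, 2, 20, labels = rep(c(1, 2), 50))
  sp <- split_64_16_20(x, fold = 1, seed = 11)
  expect_length(sp$train_idx, 64)
  expect_length(sp$val_idx, 16)
  expect_length(sp$test_idx, 20)
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_length(intersect(sp$val_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx, sp$test_idx), 1:100)
  # stratification within +/- 1 trial of the 50% global proportion
  for (part in list(sp$train_idx, sp$val_idx, sp$test_idx)) {
    n1 <- sum(x$labels[part] == 1)
    expect_lte(abs(n1 - length(part) / 2), 1)
  }
  expect_identical(split_64_16_20(x, 1, seed = 11), sp)
  expect_false(identical(split_64_16_20(x, 1, seed = 12)$test_idx, sp$test_idx))
})

test_that("five folds' test sets tile the trials exactly once", {
  x <- make_epochs(50, 2, 20, labels = rep(c(1, 2), 25))
  tests <- unlist(lapply(1:5, function(f)
    split_64_16_20(x, f, seed = 3)$test_idx))
  expect_identical(sort(tests), 1:50)
})
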