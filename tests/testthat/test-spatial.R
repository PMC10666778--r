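test_that("class covariances average trial Gram matrices", {
  dat <- array(0, c(2, 2, 2))
  dat[1, , ] <- rbind(c(1, 1), c(0, 0))
  dat[2, , ] <- rbind(c(0, 0), c(1, 1))
  x <- eeg_epochs(dat, 100, c(1, 2))
  cv <- class_covariances(x, trace_normalize = FALSE)
  expect_equal(cv$gamma1, rbind(c(2, 0), c(0, 0)))
  expect_equal(cv$gamma2, rbind(c(0, 0), c(0, 2)))

  # amplitude scaling law
  sim <- tiny_sim()
  x2 <- sim$epochs; x2$data <- 2 * x2$data
  raw1 <- class_covariances(sim$epochs, FALSE)
  raw2 <- class_covariances(x2, FALSE)
  expect_equal(raw2$gamma1, 4 * raw1$gamma1)
  norm1 <- class_covariances(sim$epochs, TRUE)
  norm2 <- class_covariances(x2, TRUE)
  expect_equal(norm2$gamma1, norm1$gamma1)

  # symmetric PSD
  ev <- eigen(norm1$gamma1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  x_one <- select_trials(sim$epochs, which(sim$epochs$labels == 1))
  expect_error(class_covariances(x_one), "both classes")
})

test_that("delay embedding stacks a lagged copy", {
  dat <- array(0, c(2, 1, 4)); dat[1, 1, ] <- 1:4; dat[2, 1, ] <- 5:8
  x <- eeg_epochs(dat, 10, c(1, 2))
  de <- delay_embed(x, 1)
  expect_equal(matrix(de$data[1, , ], nrow = 2), rbind(2:4, 1:3))
  expect_identical(de$channel_names, c("ch1", "ch1_d1"))
  expect_equal(de$t_start, 0.1)
  expect_error(delay_embed(x, 0), "tau")
  expect_error(delay_embed(x, 4), "tau")
  # shape law through covariance estimation
  sim <- tiny_sim()
  cv <- class_covariances(delay_embed(sim$epochs, 2))
  expect_identical(dim(cv$gamma1), c(12L, 12L))
})

test_that("CSP solves the generalized eigenproblem", {
  cov <- structure(list(gamma1 = diag(c(4, 1)), gamma2 = diag(c(1, 4)),
                        n1 = 1, n2 = 1, trace_normalized = FALSE),
                   class = "cov_set")
  m <- fit_csp(cov, K = 1)
  expect_equal(m$eigvals, c(4, 0.25), tolerance = 1e-6)
  expect_equal(abs(m$W[, 1] / sqrt(sum(m$W[, 1]^2))), c(1, 0), tolerance = 1e-6)

  # identical classes are inseparable
  g <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  cov2 <- structure(list(gamma1 = g, gamma2 = g, n1 = 2, n2 = 2,
                         trace_normalized = FALSE), class = "cov_set")
  expect_equal(fit_csp(cov2, K = 2)$eigvals, rep(1, 4), tolerance = 1e-6)

  # brute-force explicit-inverse oracle on random SPD pairs
  set.seed(13)
  for (i in 1:10) {
    C <- sample(3:8, 1)
    g1 <- crossprod(matrix(rnorm(C * C * 4), ncol = C)) / C
    g2 <- crossprod(matrix(rnorm(C * C * 4), ncol = C)) / C
    cv <- structure(list(gamma1 = g1, gamma2 = g2, n1 = 1, n2 = 1,
                         trace_normalized = FALSE), class = "cov_set")
    K <- floor(C / 2)
    m <- fit_csp(cv, K)
    brute <- sort(Re(eigen(solve(g2) %*% g1)$values), decreasing = TRUE)
    expect_equal(m$eigvals, brute[c(1:K, (C - K + 1):C)], tolerance = 1e-6)
  }
})

test_that("penalty matrices are the class means of X L X'", {
  sim <- tiny_sim()
  g <- build_graph(n_samples(sim$epochs), 2)
  P <- penalty_matrices(sim$epochs, g)
  # dense oracle
  for (cl in 1:2) {
    idx <- which(sim$epochs$labels == cl)
    dense <- Reduce(`+`, lapply(idx, function(i) {
      X <- matrix(sim$epochs$data[i, , ], nrow = 6)
      X %*% g$L %*% t(X)
    })) / length(idx)
    expect_equal(P[[cl]], dense, tolerance = 1e-9)
    ev <- eigen(P[[cl]], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(P[[cl]])))
  }
  # constant-in-time trials are annihilated
  xc <- make_epochs(2, 2, 20, labels = c(1, 2),
                    fill = function(i, c) rep(i + c, 20))
  Pc <- penalty_matrices(xc, build_graph(20, 3))
  expect_equal(max(abs(Pc$P1)), 0, tolerance = 1e-20)
  # single channel: w'Pw equals z'Lz for that trial's series
  x1 <- make_epochs(2, 1, 30, labels = c(1, 2))
  g1 <- build_graph(30, 4)
  P1 <- penalty_matrices(x1, g1)
  z <- x1$data[1, 1, ]
  expect_equal(drop(P1$P1), drop(crossprod(z, g1$L %*% z)), tolerance = 1e-9)
  expect_error(penalty_matrices(x1, build_graph(29, 1)), "samples")
})

test_that("M interpolates covariance and penalty and stays SPD", {
  sim <- tiny_sim()
  cv <- class_covariances(sim$epochs)
  g <- build_graph(n_samples(sim$epochs), 1)
  P <- penalty_matrices(sim$epochs, g)
  M0 <- build_M(cv, P$P1, P$P2, beta = 0)
  expect_equal(M0, vpcsp:::ridge_load(cv$gamma2), tolerance = 1e-12)
  # beta -> 1: covariance contributes < 0.2% of the trace
  M99 <- build_M(cv, P$P1, P$P2, beta = 0.999)
  covpart <- 0.001 * cv$gamma2 / sum(diag(cv$gamma2)) * sum(diag(cv$gamma2))
  expect_lt(sum(diag(covpart)) / sum(diag(M99)), 0.002)
  for (b in c(0, 0.5, 0.99)) {
    M <- build_M(cv, P$P1, P$P2, b)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_silent(chol(M))
  }
  expect_error(build_M(cv, P$P1[1:3, 1:3], P$P2, 0.5), "dimension")
  expect_error(build_M(cv, P$P1, P$P2, 1), "beta")
})

test_that("beta = 0 reduces VPCSP to CSP exactly", {
  for (s in 1:5) {
    sim <- tiny_sim(seed = s)
    m0 <- vpcsp(sim$epochs, beta = 0, K = 2)
    mc <- fit_csp(class_covariances(sim$epochs), K = 2)
    expect_equal(m0$eigvals, mc$eigvals, tolerance = 1e-6)
    # selected subspaces coincide: principal angles ~ 0
    qa <- qr.Q(qr(m0$W)); qb <- qr.Q(qr(mc$W))
    angles <- acos(pmin(svd(crossprod(qa, qb))$d, 1))
    expect_lt(max(angles), 1e-4)
  }
})

test_that("VPCSP filters satisfy the eigen-equation and normalization", {
  sim <- tiny_sim(seed = 3)
  m <- vpcsp(sim$epochs, beta = 0.7, l = 2, K = 2)
  for (j in seq_len(ncol(m$W))) {
    w <- m$W[, j]
    resid <- m$gamma1 %*% w - m$eigvals[j] * (m$M %*% w)
    expect_lt(sqrt(sum(resid^2)), 1e-7 * sqrt(sum((m$gamma1 %*% w)^2)))
    expect_equal(drop(crossprod(w, m$M %*% w)), 1, tolerance = 1e-6)
  }
  # eigenvalues match explicit-inverse brute force
  brute <- sort(Re(eigen(solve(m$M) %*% m$gamma1)$values), decreasing = TRUE)
  expect_equal(m$eigvals, brute[c(1, 2, 5, 6)], tolerance = 1e-7)
  # cumulative mode runs and differs from single mode
  mq <- vpcsp(sim$epochs, beta = 0.7, spacing_mode = "cumulative", q = 3, K = 2)
  expect_false(isTRUE(all.equal(mq$eigvals, m$eigvals)))
  expect_error(vpcsp(sim$epochs, K = 4), "channels")
})

test_that("noise-free fit recovers the discriminative mixing column", {
  sim <- generate_mi_eeg(synth_config(n_trials_per_class = 20, n_channels = 6,
                                      fs = 100, duration = 2, noise_sigma = 0,
                                      erd_ratio = 4, seed = 8))
  m <- vpcsp(sim$epochs, beta = 0, K = 2)
  expect_gt(cosine_sim(m$patterns[, 1], sim$truth$mixing[, 1]), 0.99)
})

test_that("projection and log-variance features obey their contracts", {
  sim <- tiny_sim()
  m <- vpcsp(sim$epochs, beta = 0.5, l = 1, K = 2)
  z <- project_epochs(sim$epochs, m)
  expect_identical(dim(z), c(30L, 4L, 100L))
  # identity projection on a model with W = I
  m_id <- m; m_id$W <- diag(6); m_id$channel_count <- 6L
  z_id <- project_epochs(sim$epochs, m_id)
  expect_equal(z_id, sim$epochs$data, ignore_attr = TRUE)
  # linearity in X
  x2 <- sim$epochs; x2$data <- 3 * x2$data
  expect_equal(project_epochs(x2, m), 3 * z)

  f <- logvar_features(z)
  expect_identical(dim(f), c(30L, 4L))
  expect_equal(rowSums(exp(f)), rep(1, 30), tolerance = 1e-12)
  # hand example: variances (3, 1)
  zz <- array(0, c(1, 2, 4))
  zz[1, 1, ] <- c(0, 2, 0, 2) * sqrt(3)
  zz[1, 2, ] <- c(0, 2, 0, 2)
  expect_equal(drop(logvar_features(zz)), c(log(0.75), log(0.25)))
  # equal variances -> log(1/2K)
  ze <- array(0, c(1, 4, 4))
  ze[1, , ] <- matrix(rep(c(0, 1, 0, 1), 4), 4, byrow = TRUE)
  expect_equal(drop(logvar_features(ze)), rep(log(0.25), 4))
  zconst <- array(5, c(1, 2, 10))
  expect_error(logvar_features(zconst), "constant")
  # wrong channel count
  expect_error(project_epochs(make_epochs(2, 3, 50), m), "channels")
})

test_that("features and eigenvalues are amplitude-scale invariant", {
  sim <- tiny_sim(seed = 6)
  x2 <- sim$epochs; x2$data <- 17 * x2$data
  m1 <- vpcsp(sim$epochs, beta = 0.5, l = 1, K = 2)
  m2 <- vpcsp(x2, beta = 0.5, l = 1, K = 2)
  expect_equal(m1$eigvals, m2$eigvals, tolerance = 1e-8)
  f1 <- predict(m1, sim$epochs)
  f2 <- predict(m1, x2)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("penalty at the top filter shrinks as beta grows under artifacts", {
  monotone <- 0
  for (s in 1:10) {
    sim <- generate_mi_eeg(synth_config(n_trials_per_class = 20, n_channels = 8,
                                        fs = 100, duration = 1.5,
                                        noise_sigma = 4, artifact_rate = 0.1,
                                        seed = s))
    xb <- bandpass(sim$epochs, band_spec(8, 32))
    g <- build_graph(n_samples(xb), 1)
    P <- Reduce(`+`, penalty_matrices(xb, g))
    pen <- vapply(c(0, 0.25, 0.5, 0.75), function(b) {
      w <- vpcsp(xb, beta = b, l = 1, K = 2)$W[, 1]
      drop(crossprod(w, P %*% w))
    }, numeric(1))
    monotone <- monotone + all(diff(pen) <= 1e-9 * max(pen))
  }
  expect_gte(monotone, 8)
})

test_that("two-problem mode returns filters from both eigenproblems", {
  sim <- tiny_sim(seed = 2)
  m <- vpcsp(sim$epochs, beta = 0.5, l = 1, K = 2, two_problem = TRUE)
  expect_identical(ncol(m$W), 4L)
  expect_true(all(is.finite(m$eigvals)))
})
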