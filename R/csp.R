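# Spatial filtering: classical common spatial patterns (CSP) and the
# variance-characteristic-preserving variant (VPCSP).
#
# CSP finds directions w maximizing the Rayleigh quotient
# (w' G1 w)/(w' G2 w) of the two class covariances, via the generalized
# eigenproblem G1 w = lambda G2 w.  VPCSP replaces the denominator with
#   M = (1 - beta) G2 + beta (X1 L X1' + X2 L X2')
# where L is the Laplacian of the interval-l time-point graph, so filters
# whose projected series are spiky at the graph's spacings are penalized.

# Generalized symmetric-definite eigensolver via Cholesky whitening of B.
# Returns eigenvalues in decreasing order; vectors satisfy w' B w = 1.
geigen_spd <- function(A, B) {
  R <- tryCatch(chol(B), error = function(e)
    stop(errorCondition("matrix not positive definite (Cholesky failed)",
                        class = c("vpcsp_numerical_error", "error"))))
  Ri <- backsolve(R, diag(nrow(B)))
  S <- crossprod(Ri, A) %*% Ri
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, vectors = Ri %*% e$vectors)
}

ridge_load <- function(M, eps = 1e-8) {
  C <- nrow(M)
  scale <- sum(diag(M)) / C
  if (scale <= 0) scale <- 1
  M + diag(eps * scale, C)
}

check_psd <- function(M, name, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(sum(diag(M)), 1))
    stop(errorCondition(sprintf("matrix '%s' is not positive semidefinite", name),
                        class = c("vpcsp_numerical_error", "error")))
  invisible(M)
}

#' Per-class spatial covariance matrices
#'
#' Averages the trial-wise Gram matrices `X_i X_i'` within each class.  With
#' `trace_normalize = TRUE` every trial's Gram matrix is divided by its trace
#' first, removing trial-to-trial amplitude differences.
#'
#' @param x an [eeg_epochs] object with both classes present.
#' @param trace_normalize normalize each trial to unit trace? Default `TRUE`.
#' @return a `cov_set` list: `gamma1`, `gamma2` (C x C), `n1`, `n2`,
#'   `trace_normalized`.
#' @export
class_covariances <- function(x, trace_normalize = TRUE) {
  check_two_classes(x)
  one_class <- function(cl) {
    idx <- which(x$labels == cl)
    C <- n_channels(x)
    G <- matrix(0, C, C)
    for (i in idx) {
      X <- trial_matrix(x, i)
      XX <- tcrossprod(X)
      if (trace_normalize) XX <- XX / sum(diag(XX))
      G <- G + XX
    }
    G <- G / length(idx)
    (G + t(G)) / 2
  }
  structure(list(gamma1 = one_class(1L), gamma2 = one_class(2L),
                 n1 = sum(x$labels == 1L), n2 = sum(x$labels == 2L),
                 trace_normalized = isTRUE(trace_normalize)),
            class = "cov_set")
}

#' Delay-embed epoched EEG
#'
#' Stacks each epoch with a copy of itself delayed by `tau` samples,
#' doubling the channel dimension so that spatial filters can act
#' spectrally (the classic spatio-spectral-pattern construction).  The first
#' `tau` samples are dropped so both blocks align.
#'
#' @param x an [eeg_epochs] object.
#' @param tau delay in samples, `0 < tau < n_samples`. Default 1.
#' @return an [eeg_epochs] with `2C` channels and `n_samples - tau` samples;
#'   delayed channels are suffixed `"_d<tau>"`.
#' @export
delay_embed <- function(x, tau = 1L) {
  Tn <- n_samples(x)
  if (!is_count(tau) || tau < 1L || tau >= Tn)
    abort_validation(sprintf("`tau` must be an integer in 1 .. %d", Tn - 1L))
  tau <- as.integer(tau)
  orig <- x$data[, , (tau + 1):Tn, drop = FALSE]
  lagged <- x$data[, , 1:(Tn - tau), drop = FALSE]
  d <- dim(orig)
  out <- array(NA_real_, c(d[1], 2L * d[2], d[3]))
  out[, 1:d[2], ] <- orig
  out[, (d[2] + 1):(2 * d[2]), ] <- lagged
  eeg_epochs(out, x$fs, x$labels,
             c(x$channel_names, paste0(x$channel_names, "_d", tau)),
             t_start = x$t_start + tau / x$fs)
}

#' Per-class Laplacian penalty matrices
#'
#' For the graph `g` over time points, computes `P_n`, the class-`n` mean of
#' the trial-wise quadratic-form matrices `X_i L X_i'`.  For any filter `w`,
#' `w' P_n w` is the class-mean smoothness penalty (up to the factor 2 of the
#' ordered-pair sum) of the projected series `w' X_i`.
#'
#' @param x an [eeg_epochs] object.
#' @param g a `graph_spec` with `g$T == n_samples(x)`.
#' @return list of two C x C symmetric PSD matrices `P1`, `P2`.
#' @export
penalty_matrices <- function(x, g) {
  if (!inherits(g, "graph_spec")) abort_validation("`g` must be graph_spec")
  if (g$T != n_samples(x))
    abort_validation(sprintf("graph has T = %d nodes but epochs have %d samples",
                             g$T, n_samples(x)))
  one_class <- function(cl) {
    idx <- which(x$labels == cl)
    C <- n_channels(x)
    P <- matrix(0, C, C)
    for (i in idx) P <- P + penalty_quadform(trial_matrix(x, i), g)
    P / max(length(idx), 1L)
  }
  list(P1 = one_class(1L), P2 = one_class(2L))
}

#' Penalized denominator matrix of the VPCSP eigenproblem
#'
#' Forms `M = (1 - beta) * G_other + beta * (P1 + P2)` plus a small ridge.
#' With `trace_normalize = TRUE` (default) the covariance term and the summed
#' penalty term are each scaled to unit trace before combination — the two
#' terms otherwise live on very different scales (the penalty grows with
#' graph degree) and `beta` would not be comparable across datasets — and the
#' result is rescaled by `trace(G_other)` so that `beta = 0` reproduces the
#' plain covariance exactly.
#'
#' @param cov a `cov_set` from [class_covariances()].
#' @param P1,P2 per-class penalty matrices from [penalty_matrices()].
#' @param beta penalty weight in `[0, 1)`.
#' @param target_class which class's variance the numerator maximizes (the
#'   denominator uses the other class's covariance). Default 1.
#' @param trace_normalize balance the covariance and penalty scales? Default
#'   `TRUE`.
#' @return a symmetric positive definite C x C matrix.
#' @export
build_M <- function(cov, P1, P2, beta, target_class = 1L,
                    trace_normalize = TRUE) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1)
    abort_validation("`beta` must lie in [0, 1)")
  G_other <- if (target_class == 1L) cov$gamma2 else cov$gamma1
  if (!all(dim(P1) == dim(G_other)) || !all(dim(P2) == dim(G_other)))
    abort_validation("penalty matrices and covariance differ in dimension")
  P <- P1 + P2
  if (trace_normalize) {
    trG <- sum(diag(G_other))
    trP <- sum(diag(P))
    Pn <- if (trP > 0) P / trP else P * 0
    M <- ((1 - beta) * G_other / trG + beta * Pn) * trG
  } else {
    M <- (1 - beta) * G_other + beta * P
  }
  M <- (M + t(M)) / 2
  ridge_load(M)
}

select_extremal <- function(ge, K) {
  C <- length(ge$values)
  if (2L * K > C)
    abort_validation(sprintf("2K = %d filters requested but only %d channels",
                             2L * K, C))
  idx <- c(seq_len(K), (C - K + 1L):C)       # K largest then K smallest
  W <- ge$vectors[, idx, drop = FALSE]
  # canonical sign: largest-magnitude entry positive
  for (j in seq_len(ncol(W))) {
    m <- which.max(abs(W[, j]))
    if (W[m, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, values = ge$values[idx])
}

new_spatial_filters <- function(W, values, cov, M, config, subclass) {
  patterns <- (cov$gamma1 + cov$gamma2) %*% W / 2
  structure(list(W = W, eigvals = values, patterns = patterns,
                 M = M, config = config, channel_count = nrow(W)),
            class = c(subclass, "spatial_filters"))
}

#' Classical CSP filters from a covariance pair
#'
#' Solves `G1 w = lambda G2 w` (symmetric-definite solver after a small ridge
#' on `G2`) and keeps the `K` largest- and `K` smallest-eigenvalue vectors,
#' normalized to `w' G2 w = 1`.
#'
#' @param cov a `cov_set` from [class_covariances()].
#' @param K number of filter pairs; `2K <= C`. Default 3.
#' @return a `csp` / `spatial_filters` object with fields `W` (C x 2K,
#'   columns ordered largest-eigenvalue first, then smallest), `eigvals`,
#'   `patterns`, `M` (the ridged denominator), `config`.
#' @export
fit_csp <- function(cov, K = 3L) {
  if (!inherits(cov, "cov_set")) abort_validation("`cov` must be a cov_set")
  if (!is_count(K) || K < 1L) abort_validation("`K` must be a positive integer")
  check_psd(cov$gamma1, "gamma1"); check_psd(cov$gamma2, "gamma2")
  B <- ridge_load(cov$gamma2)
  ge <- geigen_spd(cov$gamma1, B)
  sel <- select_extremal(ge, as.integer(K))
  cfg <- list(beta = 0, K = as.integer(K), delay_embed = FALSE,
              trace_normalize = cov$trace_normalized)
  out <- new_spatial_filters(sel$W, sel$values, cov, B, cfg, "csp")
  out$gamma1 <- cov$gamma1
  out
}

#' VPCSP configuration
#'
#' @param beta graph-penalty weight in `[0, 1)`; `beta = 0` is classical CSP.
#' @param spacing_mode `"single"` (one spacing `l`) or `"cumulative"`
#'   (Laplacians for spacings `1..q` summed).
#' @param l edge spacing in samples (single mode).
#' @param q largest spacing (cumulative mode).
#' @param K number of filter pairs (2K filters total). Default 3.
#' @param delay_embed stack a delayed copy of the signal before fitting?
#' @param tau delay in samples. Default 1.
#' @param trace_normalize per-trial covariance normalization and
#'   covariance/penalty scale balancing. Default `TRUE`.
#' @param two_problem take the "class 2" filters from a second eigenproblem
#'   with the class roles swapped instead of the low end of the single
#'   spectrum. Default `FALSE`.
#' @return a `vpcsp_config` list.
#' @export
vpcsp_config <- function(beta = 0.5, spacing_mode = c("single", "cumulative"),
                         l = 1L, q = 1L, K = 3L, delay_embed = FALSE,
                         tau = 1L, trace_normalize = TRUE,
                         two_problem = FALSE) {
  spacing_mode <- match.arg(spacing_mode)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1)
    abort_validation("`beta` must lie in [0, 1)")
  if (!is_count(l) || l < 1L) abort_validation("`l` must be an integer >= 1")
  if (!is_count(q) || q < 1L) abort_validation("`q` must be an integer >= 1")
  if (!is_count(K) || K < 1L) abort_validation("`K` must be an integer >= 1")
  if (!is_count(tau) || tau < 1L) abort_validation("`tau` must be >= 1")
  structure(list(beta = beta, spacing_mode = spacing_mode, l = as.integer(l),
                 q = as.integer(q), K = as.integer(K),
                 delay_embed = isTRUE(delay_embed), tau = as.integer(tau),
                 trace_normalize = isTRUE(trace_normalize),
                 two_problem = isTRUE(two_problem)),
            class = "vpcsp_config")
}

#' Fit variance-characteristic-preserving spatial filters
#'
#' The central fitting function.  Optionally delay-embeds the epochs, builds
#' the interval graph over the (embedded) time axis, estimates class
#' covariances and per-class Laplacian penalty matrices, forms the penalized
#' denominator `M` and solves `G1 w = lambda M w`.  The `K` largest- and `K`
#' smallest-eigenvalue vectors (normalized to `w' M w = 1`, sign-canonical)
#' are the 2K spatial filters.  With `beta = 0` this reduces exactly to
#' classical CSP.
#'
#' @param x an [eeg_epochs] object with both classes present.
#' @param config a [vpcsp_config()]; individual fields may be overridden via
#'   `...` (e.g. `vpcsp(x, beta = 0.7, l = 2)`).
#' @param ... named [vpcsp_config()] arguments overriding `config`.
#' @return an object of class `"vpcsp"` (also `"spatial_filters"`): fields
#'   `W`, `eigvals`, `patterns`, `M`, `gamma1`, `penalty` (P1 + P2), `config`,
#'   `channel_count`.  Methods: [print()], [summary()], [coef()] (the filter
#'   matrix), [predict()] (log-variance features or projected series),
#'   [plot()] (patterns).
#' @examples
#' sim <- generate_mi_eeg(synth_config(n_trials_per_class = 12, n_channels = 6,
#'                                     fs = 100, duration = 1, seed = 1))
#' m <- vpcsp(sim$epochs, beta = 0.5, l = 1, K = 2)
#' m
#' f <- predict(m, sim$epochs)          # 24 x 4 log-variance features
#' @export
vpcsp <- function(x, config = vpcsp_config(), ...) {
  dots <- list(...)
  if (length(dots))
    config <- do.call(vpcsp_config, utils::modifyList(unclass(config), dots))
  check_two_classes(x)
  if (config$delay_embed) x <- delay_embed(x, config$tau)
  Cp <- n_channels(x)
  if (2L * config$K > Cp)
    abort_validation(sprintf("2K = %d filters but only %d channels after embedding",
                             2L * config$K, Cp))
  cov <- class_covariances(x, config$trace_normalize)
  Tn <- n_samples(x)
  if (config$beta > 0) {
    g <- if (config$spacing_mode == "single") build_graph(Tn, config$l)
         else sum_laplacians(Tn, config$q)
    P <- penalty_matrices(x, g)
  } else {
    P <- list(P1 = matrix(0, Cp, Cp), P2 = matrix(0, Cp, Cp))
  }
  M <- build_M(cov, P$P1, P$P2, config$beta, target_class = 1L,
               trace_normalize = config$trace_normalize)
  ge <- geigen_spd(cov$gamma1, M)
  if (config$two_problem) {
    K <- config$K
    hi <- select_extremal(ge, K)
    M2 <- build_M(cov, P$P1, P$P2, config$beta, target_class = 2L,
                  trace_normalize = config$trace_normalize)
    ge2 <- geigen_spd(cov$gamma2, M2)
    lo <- select_extremal(ge2, K)
    W <- cbind(hi$W[, seq_len(K)], lo$W[, seq_len(K)])
    vals <- c(hi$values[seq_len(K)], lo$values[seq_len(K)])
    sel <- list(W = W, values = vals)
  } else {
    sel <- select_extremal(ge, config$K)
  }
  out <- new_spatial_filters(sel$W, sel$values, cov, M, config, "vpcsp")
  out$gamma1 <- cov$gamma1
  out$penalty <- P$P1 + P$P2
  out
}

#' Project epochs through fitted spatial filters
#'
#' Computes `Z_i = W' X_i` per trial.  If the model was fitted on
#' delay-embedded data the same embedding is applied first.
#'
#' @param x an [eeg_epochs] object.
#' @param model a `spatial_filters` object.
#' @return numeric array `[n_trials x 2K x T']`.
#' @export
project_epochs <- function(x, model) {
  if (!inherits(model, "spatial_filters"))
    abort_validation("`model` must be a spatial_filters object")
  if (isTRUE(model$config$delay_embed)) x <- delay_embed(x, model$config$tau)
  if (n_channels(x) != model$channel_count)
    abort_validation(sprintf("model expects %d channels, data has %d",
                             model$channel_count, n_channels(x)))
  d <- dim(x$data)
  nf <- ncol(model$W)
  out <- array(NA_real_, c(d[1], nf, d[3]))
  for (i in seq_len(d[1])) out[i, , ] <- crossprod(model$W, trial_matrix(x, i))
  out
}

#' Normalized log-variance features
#'
#' For each trial the feature of filter `k` is
#' `f_k = log(var(Z_k) / sum_i var(Z_i))` with population variances along
#' time, so `sum_k exp(f_k) = 1`.  Degenerate zero variances are floored at
#' `1e-12` times the largest variance.
#'
#' @param z projected series: array `[n_trials x 2K x T']` from
#'   [project_epochs()], or a single `2K x T'` matrix.
#' @return numeric matrix `[n_trials x 2K]`.
#' @export
logvar_features <- function(z) {
  if (is.matrix(z)) z <- array(z, c(1L, dim(z)))
  if (length(dim(z)) != 3L)
    abort_validation("`z` must be a [trials x filters x samples] array")
  if (dim(z)[3] < 2L) abort_validation("need at least 2 samples per series")
  nt <- dim(z)[1]; nf <- dim(z)[2]
  out <- matrix(NA_real_, nt, nf)
  for (i in seq_len(nt)) {
    v <- apply(matrix(z[i, , ], nrow = nf), 1, pop_var)
    vmax <- max(v)
    if (vmax <= 0)
      abort_validation(sprintf("trial %d: all projected series are constant", i))
    v <- pmax(v, 1e-12 * vmax)
    out[i, ] <- log(v / sum(v))
  }
  out
}

#' @export
print.spatial_filters <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<%s> %d filters on %d channels\n", class(x)[1], ncol(x$W),
              x$channel_count))
  if (!is.null(cfg$beta))
    cat(sprintf("  beta = %g%s, K = %d, delay_embed = %s\n", cfg$beta,
                if (!is.null(cfg$spacing_mode) && cfg$beta > 0)
                  sprintf(", %s (%s)", cfg$spacing_mode,
                          if (cfg$spacing_mode == "single")
                            paste0("l = ", cfg$l) else paste0("q = ", cfg$q))
                else "",
                cfg$K, isTRUE(cfg$delay_embed)))
  cat("  eigenvalues: ", paste(signif(x$eigvals, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spatial_filters <- function(object, ...) {
  res <- vapply(seq_len(ncol(object$W)), function(j) {
    w <- object$W[, j]
    num <- object$gamma1 %||% NULL
    if (is.null(num)) return(NA_real_)
    r <- num %*% w - object$eigvals[j] * (object$M %*% w)
    sqrt(sum(r^2)) / sqrt(sum((num %*% w)^2))
  }, numeric(1))
  structure(list(model = object, residuals = res,
                 norms = diag(t(object$W) %*% object$M %*% object$W)),
            class = "summary.spatial_filters")
}

#' @export
print.summary.spatial_filters <- function(x, ...) {
  print(x$model)
  cat("  w'Mw norms:    ", paste(signif(x$norms, 6), collapse = ", "), "\n")
  if (!all(is.na(x$residuals)))
    cat("  eigen residuals:", paste(signif(x$residuals, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.spatial_filters <- function(object, ...) object$W

#' @export
predict.spatial_filters <- function(object, newdata,
                                    type = c("features", "projection"), ...) {
  type <- match.arg(type)
  z <- project_epochs(newdata, object)
  if (type == "projection") z else logvar_features(z)
}

#' @export
plot.spatial_filters <- function(x, ...) {
  graphics::matplot(x$patterns, type = "h", lty = 1,
                    xlab = "channel", ylab = "pattern weight",
                    main = sprintf("%s spatial patterns", class(x)[1]), ...)
  graphics::legend("topright", legend = paste0("f", seq_len(ncol(x$patterns))),
                   col = seq_len(ncol(x$patterns)), lty = 1, cex = 0.7)
  invisible(x)
}
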