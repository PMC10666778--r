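# Sequential Bayesian hyperparameter optimization with a Gaussian-process
# surrogate and the expected-improvement acquisition.  Tunes the graph
# spacing l, the penalty weight beta and the cumulative order q (plus the
# spacing mode) against validation accuracy.

#' Hyperparameter search space
#'
#' @param l_range integer interval for the single-spacing `l`.  The upper cap
#'   defaults to 40 and is clipped to `T' - 1` at fit time.
#' @param beta_range real interval within `[0, 1)` for the penalty weight.
#' @param q_range integer interval for the cumulative spacing order.
#' @param modes spacing modes explored: subset of
#'   `c("single", "cumulative")`.  In single mode `q` is pinned to 1; in
#'   cumulative mode `l` is unused.
#' @param n_iterations optimization budget (sequential evaluations).
#'   Default 50.
#' @param n_init initial random (space-filling) evaluations before the
#'   surrogate takes over. Default 10.
#' @param seed integer seed.
#' @return a `hyper_search_space` list.
#' @export
hyper_search_space <- function(l_range = c(1L, 40L), beta_range = c(0, 0.99),
                               q_range = c(1L, 20L),
                               modes = c("single", "cumulative"),
                               n_iterations = 50L, n_init = 10L, seed = 1L) {
  if (length(l_range) != 2L || l_range[1] > l_range[2] || l_range[1] < 1)
    abort_validation("`l_range` must be a nonempty integer interval >= 1")
  if (length(beta_range) != 2L || beta_range[1] > beta_range[2] ||
      beta_range[1] < 0 || beta_range[2] >= 1)
    abort_validation("`beta_range` must be a nonempty interval within [0, 1)")
  if (length(q_range) != 2L || q_range[1] > q_range[2] || q_range[1] < 1)
    abort_validation("`q_range` must be a nonempty integer interval >= 1")
  modes <- match.arg(modes, several.ok = TRUE)
  if (!is_count(n_iterations) || n_iterations < 1L)
    abort_validation("`n_iterations` must be >= 1")
  structure(list(l_range = as.integer(round(l_range)), beta_range = beta_range,
                 q_range = as.integer(round(q_range)), modes = modes,
                 n_iterations = as.integer(n_iterations),
                 n_init = as.integer(max(1L, min(n_init, n_iterations))),
                 seed = as.integer(seed)),
            class = "hyper_search_space")
}

space_is_singleton <- function(space) {
  length(space$modes) == 1L &&
    space$l_range[1] == space$l_range[2] &&
    space$beta_range[1] == space$beta_range[2] &&
    space$q_range[1] == space$q_range[2]
}

sample_int_range <- function(a, b) if (a >= b) a else a + sample.int(b - a + 1L, 1L) - 1L

sample_point <- function(space) {
  mode <- if (length(space$modes) == 1L) space$modes else
    space$modes[sample.int(length(space$modes), 1L)]
  list(mode = mode,
       l = sample_int_range(space$l_range[1], space$l_range[2]),
       beta = stats::runif(1, space$beta_range[1], space$beta_range[2]),
       q = sample_int_range(space$q_range[1], space$q_range[2]))
}

# Encode a parameter point into [0,1]^4 for the GP.
encode_point <- function(p, space) {
  unit <- function(v, r) if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else 0.5
  c(mode = as.numeric(p$mode == "cumulative"),
    l = unit(p$l, space$l_range),
    beta = unit(p$beta, space$beta_range),
    q = unit(p$q, space$q_range))
}

gp_ei <- function(X, y, Xc, lengthscale = 0.3, noise = 1e-3, xi = 0.01) {
  ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  ys <- (y - mean(y)) / ysd
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  K <- k(X, X) + diag(noise, nrow(X))
  Kinv_y <- solve(K, ys)
  Kc <- k(Xc, X)
  mu <- drop(Kc %*% Kinv_y)
  v <- solve(K, t(Kc))
  s2 <- pmax(1 - rowSums(t(v) * Kc), 1e-12)
  s <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best - xi) / s
  (mu - best - xi) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Bayesian optimization of the VPCSP hyperparameters
#'
#' Sequentially evaluates `(mode, l, beta, q)` configurations: each
#' evaluation trains the decoding model (optionally a full filter bank) on
#' the training trials and scores accuracy on the validation trials.  After
#' `n_init` space-filling draws, proposals maximize expected improvement
#' under a Gaussian-process surrogate over the normalized parameters.
#' Deterministic for a fixed seed.  A space collapsed to a single point
#' short-circuits after one evaluation.
#'
#' @param x_train,x_val disjoint [eeg_epochs] train and validation sets.
#' @param space a [hyper_search_space()].
#' @param config fixed [vpcsp_config()] defaults for fields not searched.
#' @param clf_kind `"svm-rbf"` or `"lda"`.
#' @param bands list of [band_spec()] branches (default: single 8-32 Hz
#'   band); pass [default_bands()] for the filter-bank variant.
#' @param seed integer seed; defaults to `space$seed`.
#' @return list: `best` (mode, l, beta, q), `best_accuracy` (%), `trace`
#'   (data frame: iteration, mode, l, beta, q, val_accuracy, best_so_far).
#' @export
bayes_optimize <- function(x_train, x_val, space, config = vpcsp_config(),
                           clf_kind = c("svm-rbf", "lda"),
                           bands = list(band_spec(8, 32)),
                           seed = space$seed) {
  clf_kind <- match.arg(clf_kind)
  if (!inherits(space, "hyper_search_space"))
    abort_validation("`space` must come from hyper_search_space()")
  # clip l against the projected time axis (after band filtering/embedding)
  Tmax <- n_samples(x_train) - (if (config$delay_embed) config$tau else 0L)
  space$l_range <- pmin(space$l_range, Tmax - 1L)
  space$q_range <- pmin(space$q_range, Tmax - 1L)
  evaluate <- function(p) {
    cfg <- do.call(vpcsp_config, utils::modifyList(unclass(config), list(
      spacing_mode = p$mode, l = p$l, beta = p$beta,
      q = if (p$mode == "single") 1L else p$q)))
    m <- vpcsp_fb(x_train, bands = bands, config = cfg, clf_kind = clf_kind,
                  seed = seed)
    pred <- predict(m, x_val, type = "class")
    100 * mean(pred == x_val$labels)
  }
  with_seed(seed, {
    pts <- list(); accs <- numeric(0)
    n_iter <- if (space_is_singleton(space)) 1L else space$n_iterations
    for (it in seq_len(n_iter)) {
      p <- if (it <= space$n_init || space_is_singleton(space)) {
        sample_point(space)
      } else {
        X <- do.call(rbind, lapply(pts, encode_point, space = space))
        cand <- replicate(256, sample_point(space), simplify = FALSE)
        Xc <- do.call(rbind, lapply(cand, encode_point, space = space))
        cand[[which.max(gp_ei(X, accs, Xc))]]
      }
      accs <- c(accs, evaluate(p))
      pts[[it]] <- p
    }
    trace <- data.frame(
      iteration = seq_along(pts),
      mode = vapply(pts, `[[`, character(1), "mode"),
      l = vapply(pts, `[[`, numeric(1), "l"),
      beta = vapply(pts, `[[`, numeric(1), "beta"),
      q = vapply(pts, `[[`, numeric(1), "q"),
      val_accuracy = accs,
      best_so_far = cummax(accs))
    best <- pts[[which.max(accs)]]
    list(best = best, best_accuracy = max(accs), trace = trace)
  })
}
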