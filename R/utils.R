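# Internal helpers shared across the package.

# Validation failures get a dedicated condition class so callers (and the
# command-line wrapper) can distinguish bad input (exit 2) from bugs (exit 1).
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("vpcsp_validation_error", "error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("vpcsp_io_error", "error")))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) abort_validation("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Population variance along a vector (divide by n, not n-1): band power of a
# zero-mean projected series.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
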