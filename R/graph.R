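# Graph over projected time points: nodes are the T samples of a spatially
# projected series z, and edges join samples exactly l apart.  The quadratic
# form z' L z then sums squared differences across those edges, so minimizing
# it smooths the series at lag l while leaving shorter-range (local variance)
# structure untouched.

#' Build the interval-l time-point graph
#'
#' Nodes are time points `0 .. T-1`; an edge joins `i` and `j` exactly when
#' `|i - j|` equals one of `spacings`.  Returns the adjacency matrix `A`, the
#' degree matrix `D` and the combinatorial Laplacian `L = D - A`.
#'
#' @param T_nodes number of time points (graph nodes).
#' @param l edge spacing in samples, `1 <= l <= T_nodes - 1`.
#' @return a `graph_spec` list with `T`, `spacings`, `A`, `D`, `L`.
#' @examples
#' g <- build_graph(6, 3)    # edges (0,3), (1,4), (2,5)
#' sum(g$A) / 2              # T - l = 3 edges
#' @export
build_graph <- function(T_nodes, l) {
  if (!is_count(T_nodes) || T_nodes < 2L)
    abort_validation("`T_nodes` must be an integer >= 2")
  if (!is_count(l) || l < 1L)
    abort_validation("`l` must be an integer >= 1")
  if (l >= T_nodes)
    abort_validation(sprintf(
      "spacing l = %d admits no edges for T = %d (need l <= T - 1)", l, T_nodes))
  graph_from_spacings(as.integer(T_nodes), as.integer(l))
}

#' Cumulative multi-spacing Laplacian
#'
#' Sums the single-spacing Laplacians for `l = 1 .. q`, i.e. the graph whose
#' edges join every pair of time points at most `q` samples apart.  Using
#' several spacings constrains the projected series at multiple lags at once.
#'
#' @param T_nodes number of time points.
#' @param q largest spacing, `1 <= q <= T_nodes - 1`.
#' @return a `graph_spec` with `spacings = 1:q`.
#' @export
sum_laplacians <- function(T_nodes, q) {
  if (!is_count(T_nodes) || T_nodes < 2L)
    abort_validation("`T_nodes` must be an integer >= 2")
  if (!is_count(q) || q < 1L || q >= T_nodes)
    abort_validation(sprintf("`q` must be in 1 .. T - 1 = %d", T_nodes - 1L))
  graph_from_spacings(as.integer(T_nodes), seq_len(q))
}

graph_from_spacings <- function(T_nodes, spacings) {
  A <- matrix(0, T_nodes, T_nodes)
  idx <- seq_len(T_nodes)
  for (l in spacings) {
    i <- idx[seq_len(T_nodes - l)]
    A[cbind(i, i + l)] <- 1
    A[cbind(i + l, i)] <- 1
  }
  deg <- rowSums(A)
  D <- diag(deg, T_nodes)
  structure(list(T = T_nodes, spacings = as.integer(spacings),
                 A = A, D = D, L = D - A),
            class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf("<graph_spec> T = %d nodes, spacings {%s}, %d edges\n",
              x$T, paste(x$spacings, collapse = ", "), sum(x$A) / 2))
  invisible(x)
}

#' Smoothness penalty of a projected series
#'
#' Evaluates `R(z) = sum_{i,j} (z_i - z_j)^2 A_{ij} = 2 z' L z`, the total
#' squared difference across graph edges (each undirected edge counted twice
#' by the ordered-pair sum).  Zero for constant series; small for series that
#' vary slowly at the graph's spacings; large in the presence of transient
#' spikes.
#'
#' @param z numeric vector of length `g$T`.
#' @param g a `graph_spec`.
#' @return nonnegative scalar.
#' @export
smoothness_penalty <- function(z, g) {
  if (!inherits(g, "graph_spec")) abort_validation("`g` must be graph_spec")
  if (length(z) != g$T)
    abort_validation(sprintf("length(z) = %d but graph has T = %d nodes",
                             length(z), g$T))
  2 * drop(crossprod(z, g$L %*% z))
}

#' Dump a graph's adjacency matrix as MatrixMarket
#'
#' Debug helper: writes `g$A` as a sparse MTX file.
#'
#' @param g a `graph_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_mtx <- function(g, path) {
  Matrix::writeMM(Matrix::Matrix(g$A, sparse = TRUE), path)
  invisible(path)
}

# C x C penalty quadratic-form matrix X L X' without materializing T x T
# products: for each spacing l, with X1 = X[, 1:(T-l)] and X2 = X[, (l+1):T],
#   X A X' = X1 X2' + X2 X1'   and   X D X' = X diag(deg) X',
# so X L X' costs O(C^2 T) per spacing.
penalty_quadform <- function(X, g) {
  Tn <- ncol(X)
  deg <- diag(g$D)
  XD <- X * rep(deg, each = nrow(X))
  M <- tcrossprod(XD, X)
  for (l in g$spacings) {
    X1 <- X[, seq_len(Tn - l), drop = FALSE]
    X2 <- X[, (l + 1):Tn, drop = FALSE]
    C12 <- tcrossprod(X1, X2)
    M <- M - C12 - t(C12)
  }
  (M + t(M)) / 2
}
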