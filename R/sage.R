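#' Per-node neighbour mean
#'
#' Row `v` of the result is the arithmetic mean of `X` over `v`'s neighbours in
#' `A`; isolated nodes get a zero row.
#'
#' @param X `n x m` node feature matrix.
#' @param A `n x n` adjacency matrix (binary).
#' @return `n x m` matrix of neighbour averages.
#' @export
neighbor_mean <- function(X, A) {
  check_finite_matrix(X, "X")
  check_adjacency(A, "A")
  stop_if(nrow(X) != nrow(A), "X rows must match adjacency size", "mdgraph_shape_error")
  deg <- rowSums(A)
  NM <- A / pmax(deg, 1)       # isolated rows stay all-zero
  NM %*% X
}

# Row-normalized adjacency reused by the training fast path.
neighbor_mean_operator <- function(A) {
  A / pmax(rowSums(A), 1)
}

#' Initialize reduction parameters
#'
#' Weight of shape `(2 m) x m_out` (He-scaled normal) and zero bias for the
#' concatenated (own || neighbour-mean) features.
#'
#' @param m input feature dimension per node.
#' @param m_out reduced dimension (default 600).
#' @return List with `W` (`2m x m_out`) and `b` (length `m_out`).
#' @export
sage_params <- function(m, m_out = 600) {
  list(W = matrix(stats::rnorm(2 * m * m_out, sd = sqrt(2 / (2 * m))), 2 * m, m_out),
       b = rep(0, m_out))
}

#' One-hop neighbour-aggregation reduction
#'
#' Computes, per node, `ReLU(W' (x_v || mean of neighbour features) + b)`: a
#' single aggregation-and-projection step that reduces high-dimensional
#' channel features to the initial EEG graph feature matrix while keeping all
#' channels as nodes.
#'
#' @param X `n x m` raw node feature matrix.
#' @param A `n x n` adjacency matrix.
#' @param params list with `W` (`2m x m_out`) and `b` (length `m_out`), e.g.
#'   from [sage_params()].
#' @return `n x m_out` non-negative reduced feature matrix.
#' @export
sage_reduce <- function(X, A, params) {
  H <- cbind(X, neighbor_mean(X, A))
  stop_if(ncol(H) != nrow(params$W),
          sprintf("weight expects %d input columns, got %d", nrow(params$W), ncol(H)),
          "mdgraph_shape_error")
  relu(sweep(H %*% params$W, 2, params$b, "+"))
}
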