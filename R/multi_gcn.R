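#' Symmetric degree-normalized propagation operator
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where degrees are taken after adding
#' self-loops, so every node (including isolated ones) has a strictly positive
#' degree. The self-loop renormalization is applied inside the convolution and
#' self-loops are never stored in the adjacency itself.
#'
#' @param A `n x n` non-negative connectivity matrix (binary at the first unit,
#'   real-valued row-stochastic after structure learning).
#' @return The `n x n` normalized operator.
#' @export
gcn_norm_operator <- function(A) {
  check_adjacency(A, "A")
  stop_if(any(A < 0), "adjacency must be non-negative")
  A_hat <- A + diag(nrow(A))
  d_inv_sqrt <- 1 / sqrt(rowSums(A_hat))
  d_inv_sqrt * A_hat * rep(d_inv_sqrt, each = nrow(A))
}

#' Graph convolution layer
#'
#' One propagation step `H' = act(D^{-1/2} (A + I) D^{-1/2} H W)`: neighbouring
#' node features are averaged under symmetric degree normalization, linearly
#' transformed by `W` and passed through the activation (ReLU by default).
#'
#' @param H `n x d_in` node feature matrix.
#' @param A `n x n` connectivity matrix.
#' @param W `d_in x d_out` weight matrix.
#' @param activation `"relu"`, `"sigmoid"`, `"tanh"` or `"identity"`.
#' @param norm_op optional precomputed [gcn_norm_operator()] for `A`.
#' @return `n x d_out` updated node features.
#' @export
gcn_forward <- function(H, A, W, activation = "relu", norm_op = NULL) {
  check_finite_matrix(H, "H")
  stop_if(ncol(H) != nrow(W), "H columns must match weight rows", "mdgraph_shape_error")
  if (is.null(norm_op)) norm_op <- gcn_norm_operator(A)
  stop_if(nrow(H) != nrow(norm_op), "H rows must match adjacency size", "mdgraph_shape_error")
  Z <- norm_op %*% H %*% W
  apply_activation(Z, activation)
}

apply_activation <- function(Z, activation) {
  switch(activation,
         relu = relu(Z),
         sigmoid = sigmoid(Z),
         tanh = tanh(Z),
         identity = Z,
         stop_if(TRUE, sprintf("unknown activation '%s'", activation),
                 "mdgraph_parameter_error"))
}

#' Node information score
#'
#' Scores each node by how much its features differ from the average of its
#' neighbours: the row-wise norm of `(I - D^{-1} A) H`, where `D` holds the
#' degrees of the current connectivity without self-loops. Isolated nodes have
#' a zero neighbour average, so their score is the norm of their own feature
#' row. Nodes whose features are redundant with their neighbourhood score low
#' and are dropped first by pooling.
#'
#' @param H `n x d` node feature matrix.
#' @param A `n x n` connectivity matrix.
#' @param norm `"l1"` (Manhattan, default) or `"l2"`.
#' @return Non-negative numeric vector of length `n`.
#' @export
info_score <- function(H, A, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  check_finite_matrix(H, "H")
  check_adjacency(A, "A")
  stop_if(nrow(H) != nrow(A), "H rows must match adjacency size", "mdgraph_shape_error")
  diffs <- H - neighbor_mean_operator(A) %*% H
  if (norm == "l1") rowSums(abs(diffs)) else sqrt(rowSums(diffs^2))
}

#' Top-k node selection
#'
#' Indices of the `ceiling(pool_ratio * n)` highest-scoring nodes, ties broken
#' in favour of the lower node index, returned sorted ascending so relative
#' node order is preserved in the pooled subgraph.
#'
#' @param scores finite numeric score vector.
#' @param pool_ratio fraction of nodes to keep, in `(0, 1]`.
#' @return Sorted integer index vector (at least one index).
#' @export
top_k_select <- function(scores, pool_ratio) {
  stop_if(any(!is.finite(scores)), "scores must be finite")
  stop_if(pool_ratio <= 0 || pool_ratio > 1, "pool_ratio must be in (0, 1]",
          "mdgraph_parameter_error")
  k <- ceiling(pool_ratio * length(scores))
  sort(order(-scores, seq_along(scores))[seq_len(k)])
}

#' Pool a graph to a node subset
#'
#' Slices the feature matrix to the selected rows and the adjacency to the
#' selected rows and columns (only edges among kept nodes survive - the
#' disconnection this can cause is what structure learning repairs).
#'
#' @param H node feature matrix.
#' @param A connectivity matrix.
#' @param idx unique, in-range node indices (e.g. from [top_k_select()]).
#' @return List with pooled `H` and `A`.
#' @export
pool_graph <- function(H, A, idx) {
  stop_if(anyDuplicated(idx) > 0, "pooling indices must be unique")
  stop_if(any(idx < 1 | idx > nrow(H)), "pooling index out of range", "mdgraph_index_error")
  list(H = H[idx, , drop = FALSE], A = A[idx, idx, drop = FALSE])
}

#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Unlike softmax, sparsemax assigns exactly zero probability to low-scoring
#' entries: sort `z` descending, find the largest support size `k` with
#' `1 + k z_(k) > sum_{j<=k} z_(j)`, set the threshold
#' `tau = (sum_{j<=k} z_(j) - 1) / k` and return `max(z - tau, 0)`.
#'
#' @param z finite numeric vector.
#' @return Probability vector (non-negative, sums to 1) of the same length.
#' @export
sparsemax <- function(z) {
  stop_if(length(z) == 0, "sparsemax input must be non-empty", "mdgraph_parameter_error")
  stop_if(any(!is.finite(z)), "sparsemax input must be finite")
  drop(row_sparsemax(matrix(z, nrow = 1)))
}

# Vectorized row-wise sparsemax for an r x c matrix.
row_sparsemax <- function(Z) {
  r <- nrow(Z); cc <- ncol(Z)
  if (cc == 1) return(matrix(1, r, 1))
  o <- order(rep.int(seq_len(r), cc), -as.vector(Z), method = "radix")
  Zs <- matrix(as.vector(Z)[o], nrow = cc)   # column j = sorted row j, desc
  cs <- Zs
  for (j in 2:cc) cs[j, ] <- cs[j - 1, ] + Zs[j, ]
  supp <- 1 + seq_len(cc) * Zs > cs           # prefix property per column
  k <- .colSums(supp, cc, r)
  tau <- (cs[cbind(k, seq_len(r))] - 1) / k
  pmax(Z - tau, 0)
}

#' Sparse structure learning over a pooled subgraph
#'
#' Re-estimates connectivity among the surviving nodes: the attention score
#' between nodes `p` and `q` is `act(a . [H(p,:) || H(q,:)]) + lambda A(p,q)`,
#' and each row of scores is pushed through sparsemax, yielding a sparse
#' row-stochastic connectivity that replaces `A` for the next unit. The result
#' is intentionally not re-symmetrized: each row is a distribution over
#' targets.
#'
#' @param H `n x d` pooled node features.
#' @param A `n x n` pooled connectivity.
#' @param a attention weight vector of length `2 d`.
#' @param lambda non-negative balance between learned similarity and the
#'   existing edges.
#' @param activation activation applied to the raw attention score (bounded
#'   sigmoid by default).
#' @return `n x n` row-stochastic sparse connectivity matrix.
#' @export
structure_learning <- function(H, A, a, lambda = 1, activation = "sigmoid") {
  check_finite_matrix(H, "H")
  d <- ncol(H)
  stop_if(length(a) != 2 * d, sprintf("attention vector must have length %d", 2 * d),
          "mdgraph_shape_error")
  stop_if(lambda < 0, "lambda must be non-negative", "mdgraph_parameter_error")
  u <- drop(H %*% a[seq_len(d)])            # contribution of the source row
  v <- drop(H %*% a[d + seq_len(d)])        # contribution of the target row
  E <- apply_activation(outer(u, rep(1, nrow(H))) + outer(rep(1, nrow(H)), v),
                        activation) + lambda * A
  row_sparsemax(E)
}

#' Mean-max graph readout
#'
#' Fixed-size graph-level summary: column means concatenated with column
#' maxima of the node feature matrix (length `2 d`), invariant to node order.
#'
#' @param H `n x d` node feature matrix, `n >= 1`.
#' @return Numeric vector of length `2 * ncol(H)`.
#' @export
readout <- function(H) {
  stop_if(!is.matrix(H) || nrow(H) < 1, "readout needs at least one node",
          "mdgraph_parameter_error")
  c(colMeans(H), apply(H, 2, max))
}

#' Multi-GCN model configuration
#'
#' @param n_units number of conv/pool/structure-learning units `K` (default 3;
#'   0 reads out the initial features directly).
#' @param hidden_dim hidden width `d` of every unit.
#' @param pool_ratio fraction of nodes kept by each pooling step.
#' @param lambda structure-learning balance parameter.
#' @param activation convolution activation.
#' @param score_norm information-score norm, `"l1"` or `"l2"`.
#' @return List of class `gcn_config`.
#' @export
gcn_config <- function(n_units = 3, hidden_dim = 16, pool_ratio = 0.5,
                       lambda = 1, activation = "relu", score_norm = "l1") {
  stop_if(n_units < 0, "n_units must be >= 0", "mdgraph_parameter_error")
  stop_if(hidden_dim < 1, "hidden_dim must be >= 1", "mdgraph_parameter_error")
  structure(list(n_units = n_units, hidden_dim = hidden_dim,
                 pool_ratio = pool_ratio, lambda = lambda,
                 activation = activation, score_norm = score_norm),
            class = "gcn_config")
}

#' Initialize parameters for one conv/pool/structure-learning unit
#'
#' @param d_in,d_out convolution input/output widths.
#' @return List with `W` (`d_in x d_out`, He-scaled) and attention vector `a`
#'   (length `2 d_out`).
#' @export
unit_params <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       a = stats::rnorm(2 * d_out, sd = 0.1))
}

#' Hierarchical multi-unit graph encoder
#'
#' Runs `K` units of graph convolution, information-score top-k pooling and
#' sparsemax structure learning, reading each unit's pooled subgraph out as
#' mean || max, and returns the elementwise sum of the `K` readouts as the
#' graph embedding `f_g` (length `2 d`). With `K = 0` the embedding is the
#' readout of the initial features (length `2 m`).
#'
#' @param X0 `n x m` initial node feature matrix.
#' @param A0 `n x n` initial binary adjacency.
#' @param config a [gcn_config()].
#' @param units list of `config$n_units` parameter sets from [unit_params()]
#'   (first unit `m x d`, later units `d x d`).
#' @param norm_op0 optional precomputed [gcn_norm_operator()] for `A0`.
#' @return List with `f_g`, per-unit `readouts`, and per-unit `states`
#'   (`H`, `A`, `idx`).
#' @export
multi_gcn_forward <- function(X0, A0, config, units, norm_op0 = NULL) {
  stop_if(length(units) != config$n_units,
          sprintf("expected %d unit parameter sets, got %d", config$n_units, length(units)),
          "mdgraph_config_error")
  if (config$n_units == 0) {
    return(list(f_g = readout(X0), readouts = list(), states = list()))
  }
  H <- X0; A <- A0
  readouts <- vector("list", config$n_units)
  states <- vector("list", config$n_units)
  for (k in seq_len(config$n_units)) {
    nop <- if (k == 1) norm_op0 else NULL
    H1 <- gcn_forward(H, A, units[[k]]$W, config$activation, norm_op = nop)
    sc <- info_score(H1, A, config$score_norm)
    idx <- top_k_select(sc, config$pool_ratio)
    pooled <- pool_graph(H1, A, idx)
    S <- structure_learning(pooled$H, pooled$A, units[[k]]$a, config$lambda)
    readouts[[k]] <- readout(pooled$H)
    states[[k]] <- list(H = pooled$H, A = S, idx = idx)
    H <- pooled$H; A <- S
  }
  list(f_g = Reduce(`+`, readouts), readouts = readouts, states = states)
}
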