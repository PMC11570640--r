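# Brute-force oracles: per-node double loops over the defining formulas.

gcn_oracle <- function(H, A, W) {
  n <- nrow(A)
  A_hat <- A + diag(n)
  deg <- rowSums(A_hat)
  out <- matrix(0, n, ncol(W))
  HW <- H %*% W
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      out[p, ] <- out[p, ] + A_hat[p, q] / sqrt(deg[p] * deg[q]) * HW[q, ]
    }
  }
  pmax(out, 0)
}

info_score_oracle <- function(H, A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] != 0)
    nbm <- if (length(nb) == 0) rep(0, ncol(H))
           else colSums(A[v, nb] * H[nb, , drop = FALSE] / sum(A[v, nb]))
    sum(abs(H[v, ] - nbm))
  }, numeric(1))
}

# Independent simplex projection: solve for the threshold by root finding on
# the monotone function sum(max(z - tau, 0)) - 1.
simplex_projection_oracle <- function(z) {
  f <- function(tau) sum(pmax(z - tau, 0)) - 1
  tau <- uniroot(f, lower = min(z) - 1, upper = max(z), tol = 1e-14)$root
  pmax(z - tau, 0)
}

test_that("graph convolution matches the double-loop oracle", {
  # hand-checked: 2-node single edge with unit features is fixed by the layer
  H <- matrix(1, 2, 1)
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(gcn_forward(H, A, matrix(1)), matrix(1, 2, 1))
  # single node: normalization reduces to the identity
  expect_equal(gcn_forward(matrix(c(2, -3), 1), matrix(0, 1, 1), diag(2)),
               matrix(c(2, 0), 1))
  for (trial in 1:200) {
    set.seed(trial)
    n <- sample(2:10, 1); d_in <- sample(1:4, 1); d_out <- sample(1:4, 1)
    A <- random_adjacency(n, seed = trial)
    H <- matrix(rnorm(n * d_in), n, d_in)
    W <- matrix(rnorm(d_in * d_out), d_in, d_out)
    expect_equal(gcn_forward(H, A, W), gcn_oracle(H, A, W), tolerance = 1e-10)
  }
})

test_that("information scores match the loop oracle and vanish on redundancy", {
  # hand computation: 2-node edge with features 0 and 2
  H <- matrix(c(0, 2), 2, 1)
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(info_score(H, A), c(2, 2))
  for (trial in 1:200) {
    set.seed(trial + 500)
    n <- sample(2:10, 1); d <- sample(1:4, 1)
    A <- random_adjacency(n, seed = trial + 500)
    H <- matrix(rnorm(n * d), n, d)
    expect_equal(info_score(H, A), info_score_oracle(H, A), tolerance = 1e-12)
  }
  # identical features on a connected regular graph: every score is zero
  ring <- build_chain_adjacency(6)
  ring[1, 6] <- ring[6, 1] <- 1      # 2-regular cycle
  Hc <- matrix(rep(c(3, -1), each = 6), 6, 2)
  expect_equal(info_score(Hc, ring), rep(0, 6))
})

test_that("top-k selection keeps the highest scores with stable ties", {
  expect_equal(top_k_select(c(3, 1, 2), 2 / 3), c(1, 3))
  expect_equal(top_k_select(c(1, 1, 1), 1 / 3), 1)
  expect_equal(top_k_select(rnorm(5), 1), 1:5)
  expect_error(top_k_select(c(1, NA), 0.5))
  expect_error(top_k_select(c(1, 2), 0), class = "mdgraph_parameter_error")
})

test_that("pooling slices features and adjacency consistently", {
  chain <- build_chain_adjacency(3)
  H <- matrix(1:6, 3, 2) * 1.0
  p <- pool_graph(H, chain, c(1, 3))
  expect_equal(p$H, H[c(1, 3), ])
  expect_equal(p$A, matrix(0, 2, 2))   # the disconnection structure learning repairs
  full <- pool_graph(H, chain, 1:3)
  expect_equal(full$H, H); expect_equal(full$A, chain)
  one <- pool_graph(H, chain, 2)
  expect_equal(dim(one$A), c(1, 1)); expect_equal(one$A[1, 1], 0)
  expect_error(pool_graph(H, chain, c(1, 4)), class = "mdgraph_index_error")
})

test_that("sparsemax equals brute-force simplex projection", {
  expect_equal(sparsemax(c(0, 0)), c(0.5, 0.5))
  expect_equal(sparsemax(c(1, 0)), c(1, 0))
  set.seed(123)
  for (trial in 1:1000) {
    n <- sample(2:16, 1)
    z <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    s <- sparsemax(z)
    expect_equal(s, simplex_projection_oracle(z), tolerance = 1e-8)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s >= 0))
  }
  expect_error(sparsemax(numeric(0)), class = "mdgraph_parameter_error")
})

test_that("sparsemax rows zero out low scores on spread inputs", {
  set.seed(77)
  zeroed <- 0
  for (trial in 1:200) {
    z <- rnorm(8, sd = 2)
    s <- sparsemax(z)
    if (any(s == 0)) zeroed <- zeroed + 1
  }
  # wide-spread rows should essentially always truncate
  expect_gt(zeroed / 200, 0.95)
})

test_that("structure learning returns sparse row-stochastic connectivity", {
  set.seed(9)
  H <- matrix(rnorm(12), 4, 3)
  A <- random_adjacency(4, seed = 9)
  S <- structure_learning(H, A, a = rnorm(6), lambda = 1)
  expect_equal(rowSums(S), rep(1, 4), tolerance = 1e-12)
  expect_true(all(S >= 0))

  # single node: trivial simplex
  expect_equal(structure_learning(matrix(1, 1, 2), matrix(0, 1, 1), rep(0, 4)),
               matrix(1, 1, 1))

  # identical features, no edges: uniform rows by symmetry
  Hc <- matrix(1, 5, 2)
  S <- structure_learning(Hc, matrix(0, 5, 5), a = rnorm(4), lambda = 1)
  expect_equal(S, matrix(1 / 5, 5, 5), tolerance = 1e-12)

  # lambda -> infinity with a = 0: mass concentrates on existing edges
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  S <- structure_learning(matrix(0, 3, 2), A, a = rep(0, 4), lambda = 1e6)
  expect_equal(S[1, ], c(0, 1, 0), tolerance = 1e-5)
  expect_equal(S[2, ], c(0.5, 0, 0.5), tolerance = 1e-5)
  expect_error(structure_learning(H, random_adjacency(4), a = rnorm(5)),
               class = "mdgraph_shape_error")
})

test_that("readout concatenates column means and maxima", {
  H <- rbind(c(1, 0), c(3, 2))
  expect_equal(readout(H), c(2, 1, 3, 2))
  # single node: mean and max are the node itself
  expect_equal(readout(matrix(c(4, -1), 1)), c(4, -1, 4, -1))
  # permutation invariance and zero input
  set.seed(6)
  H <- matrix(rnorm(20), 5, 4)
  expect_equal(readout(H[sample(5), ]), readout(H))
  expect_equal(readout(matrix(0, 4, 3)), rep(0, 6))
})

test_that("the unit stack sums readouts and keeps a fixed output length", {
  set.seed(21)
  n <- 12; m <- 6; d <- 4
  X0 <- matrix(rnorm(n * m), n, m)
  A0 <- random_adjacency(n, seed = 21)
  cfg <- gcn_config(n_units = 3, hidden_dim = d)
  units <- list(unit_params(m, d), unit_params(d, d), unit_params(d, d))
  out <- multi_gcn_forward(X0, A0, cfg, units)
  expect_length(out$f_g, 2 * d)
  expect_equal(out$f_g, Reduce(`+`, out$readouts))
  # pooling strictly decreases node count at ratio 0.5
  sizes <- vapply(out$states, function(s) nrow(s$H), 0L)
  expect_equal(sizes, c(6L, 3L, 2L))

  # K = 0: readout of the input features
  out0 <- multi_gcn_forward(X0, A0, gcn_config(n_units = 0), list())
  expect_equal(out0$f_g, readout(X0))

  # K = 1 on a single-node graph equals that unit's readout
  cfg1 <- gcn_config(n_units = 1, hidden_dim = d)
  u1 <- list(unit_params(m, d))
  o1 <- multi_gcn_forward(matrix(rnorm(m), 1, m), matrix(0, 1, 1), cfg1, u1)
  expect_equal(o1$f_g, o1$readouts[[1]])

  expect_error(multi_gcn_forward(X0, A0, cfg, units[1:2]),
               class = "mdgraph_config_error")
})

test_that("the unit stack is permutation invariant", {
  for (trial in 1:5) {
    set.seed(trial + 60)
    n <- 10; m <- 5; d <- 3
    X0 <- matrix(rnorm(n * m), n, m)
    A0 <- random_adjacency(n, seed = trial + 60)
    cfg <- gcn_config(n_units = 2, hidden_dim = d)
    units <- list(unit_params(m, d), unit_params(d, d))
    f1 <- multi_gcn_forward(X0, A0, cfg, units)$f_g
    perm <- sample(n)
    f2 <- multi_gcn_forward(X0[perm, ], A0[perm, perm], cfg, units)$f_g
    expect_equal(f2, f1, tolerance = 1e-9)
  }
})
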