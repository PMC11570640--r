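# End-to-end model mechanics: analytic gradients, determinism, invariances.

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  fx <- tiny_fixture(seed = 7, n_channels = 8, n_slices = 5, segs = 1,
                     mdd = 1, hc = 1)
  mc <- model_config(m_prime_e = 5, hidden_dim = 3, att_dim = 3,
                     eeg_units = 2, audio_units = 2, standardize = FALSE)
  params <- mdgraph:::init_params(mc, ncol(fx$samples[[1]]$eeg),
                                  ncol(fx$samples[[1]]$audio), seed = 11)
  pre <- mdgraph:::build_pre(fx, mc, 1)
  Xe <- fx$samples[[1]]$eeg; Xa <- fx$samples[[1]]$audio
  y <- 1L
  loss_fn <- function(p) {
    fw <- mdgraph:::model_forward(Xe, Xa, p, mc, pre)
    -log(fw$prob[y + 1])
  }
  fw <- mdgraph:::model_forward(Xe, Xa, params, mc, pre)
  gr <- mdgraph:::zero_grads(params)
  mdgraph:::model_backward(fw, y, params, mc, pre, gr)
  eps <- 1e-6
  set.seed(99)
  for (nm in names(params)) {
    v <- params[[nm]]
    for (ii in sample(seq_along(v), min(length(v), 6))) {
      p2 <- params; p2[[nm]][ii] <- v[ii] + eps
      p3 <- params; p3[[nm]][ii] <- v[ii] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("the internal forward agrees with the composed public operations", {
  set.seed(13)
  fx <- tiny_fixture(seed = 5, n_channels = 10, n_slices = 6, segs = 1,
                     mdd = 1, hc = 1)
  mc <- model_config(m_prime_e = 6, hidden_dim = 4, att_dim = 4,
                     eeg_units = 3, audio_units = 2, standardize = FALSE)
  params <- mdgraph:::init_params(mc, ncol(fx$samples[[1]]$eeg),
                                  ncol(fx$samples[[1]]$audio), seed = 3)
  pre <- mdgraph:::build_pre(fx, mc, 1)
  s <- fx$samples[[1]]
  fw <- mdgraph:::model_forward(s$eeg, s$audio, params, mc, pre)

  # rebuild the EEG branch from the exported building blocks
  X0 <- sage_reduce(s$eeg, fx$A_eeg, list(W = params$e_sage_W, b = params$e_sage_b))
  att <- node_attention(X0, list(W = params$e_att_W, b = params$e_att_b,
                                 v = params$e_att_v))
  cfg <- gcn_config(n_units = 3, hidden_dim = 4)
  units <- lapply(1:3, function(k) list(W = params[[paste0("e_u", k, "_W")]],
                                        a = params[[paste0("e_u", k, "_a")]]))
  gg <- multi_gcn_forward(X0, fx$A_eeg, cfg, units)
  emb_e <- assemble_embedding(att$f_b, gg$f_g)
  expect_equal(fw$e$f_emb, emb_e$f_embedding, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fw$e$alpha, att$alpha, tolerance = 1e-12, ignore_attr = TRUE)

  # audio branch: initial features go straight into attention + units
  att_a <- node_attention(s$audio, list(W = params$a_att_W, b = params$a_att_b,
                                        v = params$a_att_v))
  cfg_a <- gcn_config(n_units = 2, hidden_dim = 4)
  units_a <- lapply(1:2, function(k) list(W = params[[paste0("a_u", k, "_W")]],
                                          a = params[[paste0("a_u", k, "_a")]]))
  gg_a <- multi_gcn_forward(s$audio, fx$A_audio, cfg_a, units_a)
  expect_equal(fw$a$f_emb, c(att_a$f_b, gg_a$f_g), tolerance = 1e-12,
               ignore_attr = TRUE)

  # and the head reproduces the final probabilities
  head <- fuse_and_classify(emb_e, assemble_embedding(att_a$f_b, gg_a$f_g),
                            list(w_e = params$e_gate, w_a = params$a_gate,
                                 W = params$clf_W, b = params$clf_b))
  expect_equal(fw$prob, head$prob, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  fx <- tiny_fixture(seed = 9)
  mc <- tiny_model_config()
  m1 <- train_model(fx, mc, seed = 4)
  m2 <- train_model(fx, mc, seed = 4)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  p1 <- predict_model(m1, fx)
  p2 <- predict_model(m2, fx)
  expect_identical(p1, p2)
  # a different seed gives a different model
  m3 <- train_model(fx, mc, seed = 5)
  expect_false(identical(m3$params, m1$params))
})

test_that("the forward pass is invariant to EEG channel relabeling", {
  fx <- tiny_fixture(seed = 11, n_channels = 10)
  mc <- tiny_model_config(epochs = 2)
  m <- train_model(fx, mc, seed = 2, compute_attention = FALSE)
  p_ref <- predict_model(m, fx, indices = 1:4)

  set.seed(31)
  perm <- sample(nrow(fx$montage))
  fx_perm <- fx
  fx_perm$A_eeg <- fx$A_eeg[perm, perm]
  fx_perm$samples <- lapply(fx$samples, function(s) {
    s$eeg <- s$eeg[perm, , drop = FALSE]
    s
  })
  m_perm <- m
  m_perm$std$mu_e <- m$std$mu_e[perm, , drop = FALSE]
  m_perm$std$sd_e <- m$std$sd_e[perm, , drop = FALSE]
  m_perm$pre$eeg <- list(N0 = gcn_norm_operator(fx_perm$A_eeg),
                         A0 = fx_perm$A_eeg,
                         NM = mdgraph:::neighbor_mean_operator(fx_perm$A_eeg),
                         NM0 = mdgraph:::neighbor_mean_operator(fx_perm$A_eeg))
  p_perm <- predict_model(m_perm, fx_perm, indices = 1:4)
  expect_equal(p_perm, p_ref, tolerance = 1e-9)
})

test_that("a trained model round-trips through the JSON archive", {
  fx <- tiny_fixture(seed = 19)
  mc <- tiny_model_config(epochs = 2)
  m <- train_model(fx, mc, seed = 8)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$config$hidden_dim, mc$hidden_dim)
  expect_equal(back$seed, 8)
  for (nm in names(m$params)) {
    expect_equal(back$params[[nm]], unname(m$params[[nm]]), tolerance = 1e-12,
                 ignore_attr = TRUE, label = nm)
  }
  p1 <- predict_model(m, fx, indices = 1:5)
  p2 <- predict_model(back, fx, indices = 1:5)
  expect_equal(p2, p1, tolerance = 1e-10)
})

test_that("class probabilities are well-formed and training loss decreases", {
  fx <- tiny_fixture(seed = 15, effect_size = 1.5)
  mc <- tiny_model_config(epochs = 4)
  m <- train_model(fx, mc, seed = 6)
  expect_lt(m$history[length(m$history)], m$history[1])
  p <- predict_model(m, fx)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(m$attention$channel, nrow(fx$montage))
  expect_equal(sum(m$attention$channel), 1, tolerance = 1e-9)
})
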