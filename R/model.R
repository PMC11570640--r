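#' Full model configuration
#'
#' Collects every tunable of the multimodal classifier: the per-modality
#' graph-encoder depths, hidden widths, pooling ratio and structure-learning
#' balance, plus the training schedule (Adam, minibatch cross-entropy, early
#' stopping on a training-loss plateau).
#'
#' @param eeg_units,audio_units number of conv/pool/structure-learning units
#'   per modality (0 reads out the initial features directly).
#' @param hidden_dim hidden width `d` of the graph units.
#' @param att_dim hidden width of the node-attention scorer.
#' @param pool_ratio fraction of nodes kept per pooling step.
#' @param lambda structure-learning balance parameter.
#' @param m_prime_e reduced EEG feature dimension after the neighbour
#'   aggregation step.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_tol relative training-loss improvement below which an
#'   epoch counts towards the plateau.
#' @param patience plateau epochs tolerated before stopping.
#' @param standardize standardize features using training-set statistics.
#' @param score_norm information-score norm (`"l1"` or `"l2"`).
#' @return List of class `model_config`.
#' @export
model_config <- function(eeg_units = 3, audio_units = 3, hidden_dim = 16,
                         att_dim = 16, pool_ratio = 0.5, lambda = 1,
                         m_prime_e = 600, lr = 1e-3, epochs = 100,
                         batch_size = 32, early_stop_tol = 1e-4, patience = 3,
                         standardize = TRUE, score_norm = "l1") {
  stop_if(eeg_units < 0 || audio_units < 0, "unit counts must be >= 0",
          "mdgraph_parameter_error")
  structure(list(eeg_units = eeg_units, audio_units = audio_units,
                 hidden_dim = hidden_dim, att_dim = att_dim,
                 pool_ratio = pool_ratio, lambda = lambda,
                 m_prime_e = m_prime_e, lr = lr, epochs = epochs,
                 batch_size = batch_size, early_stop_tol = early_stop_tol,
                 patience = patience, standardize = standardize,
                 score_norm = score_norm),
            class = "model_config")
}

# Embedding length of one modality: f_b (m) plus f_g (2d, or 2m when K = 0).
embedding_length <- function(m, n_units, d) {
  m + if (n_units > 0) 2 * d else 2 * m
}

#' Model configuration sized for the synthetic fixture
#'
#' The package default keeps the reduced EEG dimension at 600, matching the
#' scale of real high-density recordings. The synthetic fixture carries only
#' 16 band-power-like features per channel, so projecting it to 600 dimensions
#' would add cost without information; this configuration reduces to 64
#' dimensions, uses 16-unit hidden widths and trains for two minibatch-Adam
#' epochs at learning rate 3e-3, which is sufficient for convergence on the
#' strongly separable fixture. These are the problem sizes used by the
#' package's own evaluation runs.
#'
#' @param ... overrides forwarded to [model_config()].
#' @return A [model_config()].
#' @export
fixture_model_config <- function(...) {
  args <- utils::modifyList(list(m_prime_e = 64, hidden_dim = 16, att_dim = 16,
                                 epochs = 2, batch_size = 32, lr = 3e-3),
                            list(...))
  do.call(model_config, args)
}

#' Initialize all model parameters
#'
#' @param config a [model_config()].
#' @param m_e raw per-channel EEG feature dimension.
#' @param m_a audio slice feature dimension.
#' @param seed RNG seed for the parameter draw.
#' @return Flat named list of parameter arrays.
#' @export
init_params <- function(config, m_e, m_a, seed = 1) {
  set.seed(seed)
  d <- config$hidden_dim
  mpe <- config$m_prime_e
  p <- list()
  sg <- sage_params(m_e, mpe)
  p$e_sage_W <- sg$W; p$e_sage_b <- sg$b
  at <- node_attention_params(mpe, config$att_dim)
  p$e_att_W <- at$W; p$e_att_b <- at$b; p$e_att_v <- at$v
  if (config$eeg_units > 0) {
    for (k in seq_len(config$eeg_units)) {
      up <- unit_params(if (k == 1) mpe else d, d)
      p[[paste0("e_u", k, "_W")]] <- up$W
      p[[paste0("e_u", k, "_a")]] <- up$a
    }
  }
  p$e_gate <- rep(0, embedding_length(mpe, config$eeg_units, d))
  at <- node_attention_params(m_a, config$att_dim)
  p$a_att_W <- at$W; p$a_att_b <- at$b; p$a_att_v <- at$v
  if (config$audio_units > 0) {
    for (k in seq_len(config$audio_units)) {
      up <- unit_params(if (k == 1) m_a else d, d)
      p[[paste0("a_u", k, "_W")]] <- up$W
      p[[paste0("a_u", k, "_a")]] <- up$a
    }
  }
  p$a_gate <- rep(0, embedding_length(m_a, config$audio_units, d))
  z_len <- embedding_length(mpe, config$eeg_units, d) +
    embedding_length(m_a, config$audio_units, d)
  p$clf_W <- matrix(stats::rnorm(2 * z_len, sd = 0.01), 2, z_len)
  p$clf_b <- rep(0, 2)
  p
}

# ---- forward pass with cache ------------------------------------------------

# One modality: optional neighbour-aggregation reduction, node attention,
# K graph units; returns the embedding and every intermediate the backward
# pass needs.
fwd_modality <- function(X, params, prefix, n_units, config, pre, use_sage) {
  g <- function(nm) params[[paste0(prefix, "_", nm)]]
  cache <- list(use_sage = use_sage, n_units = n_units)
  if (use_sage) {
    Hcat <- if (!is.null(pre$Hcat)) pre$Hcat else cbind(X, pre$NM %*% X)
    Z0 <- Hcat %*% g("sage_W") + rep(g("sage_b"), each = nrow(Hcat))
    X0 <- relu(Z0)
    cache$Hcat <- Hcat; cache$Z0 <- Z0
  } else {
    X0 <- X
  }
  cache$X0 <- X0

  Tm <- tanh(X0 %*% g("att_W") + rep(g("att_b"), each = nrow(X0)))
  u <- Tm %*% g("att_v")
  alpha <- softmax_vec(as.vector(u))
  f_b <- as.vector(crossprod(X0, alpha))
  cache$Tm <- Tm; cache$alpha <- alpha

  if (n_units == 0) {
    amax <- max.col(t(X0), ties.method = "first")
    f_g <- c(.colMeans(X0, nrow(X0), ncol(X0)),
             X0[cbind(amax, seq_len(ncol(X0)))])
    cache$amax0 <- amax
  } else {
    H <- X0
    units <- vector("list", n_units)
    f_g <- NULL
    l1 <- config$score_norm == "l1"
    for (k in seq_len(n_units)) {
      uc <- list()
      if (k == 1) {
        N <- pre$N0
        A_in <- pre$A0
        Mop <- pre$NM0
      } else {
        S_prev <- units[[k - 1]]$S
        A_hat <- S_prev + diag(nrow(S_prev))
        deg <- .rowSums(A_hat, nrow(A_hat), nrow(A_hat))
        dinv <- 1 / sqrt(deg)
        N <- dinv * A_hat * rep(dinv, each = nrow(A_hat))
        uc$deg <- deg; uc$dinv <- dinv
        A_in <- S_prev
        Mop <- S_prev   # rows of a sparsemax output sum to 1
      }
      W <- g(paste0("u", k, "_W")); a <- g(paste0("u", k, "_a"))
      M <- H %*% W
      Z <- N %*% M
      H1 <- relu(Z)
      diffs <- H1 - Mop %*% H1
      sc <- if (l1) .rowSums(abs(diffs), nrow(diffs), ncol(diffs))
            else sqrt(.rowSums(diffs^2, nrow(diffs), ncol(diffs)))
      idx <- top_k_select(sc, config$pool_ratio)
      H2 <- H1[idx, , drop = FALSE]
      A2 <- A_in[idx, idx, drop = FALSE]
      d <- ncol(H2)
      n2 <- nrow(H2)
      usl <- as.vector(H2 %*% a[seq_len(d)])
      vsl <- as.vector(H2 %*% a[d + seq_len(d)])
      G <- sigmoid(matrix(usl + rep(vsl, each = n2), n2, n2))
      E <- G + config$lambda * A2
      S <- row_sparsemax(E)
      amax <- max.col(t(H2), ties.method = "first")
      r_k <- c(.colMeans(H2, n2, d), H2[cbind(amax, seq_len(d))])
      f_g <- if (is.null(f_g)) r_k else f_g + r_k
      uc <- c(uc, list(N = N, H_in = H, M = M, Z = Z, H1 = H1, idx = idx,
                       H2 = H2, A2 = A2, G = G, S = S, amax = amax))
      units[[k]] <- uc
      H <- H2
    }
    cache$units <- units
  }
  cache$f_b <- f_b; cache$f_g <- f_g
  cache$f_emb <- c(f_b, f_g)
  cache
}

# Full forward pass for one sample; `pre` carries the precomputed operators.
model_forward <- function(sample_e, sample_a, params, config, pre) {
  ce <- fwd_modality(sample_e, params, "e", config$eeg_units, config,
                     pre$eeg, use_sage = TRUE)
  ca <- fwd_modality(sample_a, params, "a", config$audio_units, config,
                     pre$audio, use_sage = FALSE)
  sw_e <- sigmoid(params$e_gate); sw_a <- sigmoid(params$a_gate)
  ge <- ce$f_emb * sw_e; ga <- ca$f_emb * sw_a
  z <- c(ge, ga)
  logits <- drop(params$clf_W %*% z + params$clf_b)
  prob <- softmax_vec(logits)
  list(prob = prob, logits = logits, z = z, e = ce, a = ca,
       sw_e = sw_e, sw_a = sw_a)
}

# ---- backward pass ----------------------------------------------------------

row_sparsemax_bwd <- function(dS, S) {
  supp <- S > 0
  v <- rowSums(dS * supp) / rowSums(supp)
  supp * (dS - v)   # v recycles down columns: per-row support mean
}

# Accumulates gradients for one modality into environment `gr`.
bwd_modality <- function(df_emb, cache, params, prefix, config, pre, gr) {
  g <- function(nm) params[[paste0(prefix, "_", nm)]]
  acc <- function(nm, val) {
    key <- paste0(prefix, "_", nm)
    gr[[key]] <- gr[[key]] + val
  }
  X0 <- cache$X0
  m <- ncol(X0); n <- nrow(X0)
  df_b <- df_emb[seq_len(m)]
  df_g <- df_emb[-seq_len(m)]
  dX0 <- matrix(0, n, m)

  if (cache$n_units == 0) {
    dX0 <- dX0 + matrix(rep(df_g[seq_len(m)] / n, each = n), n, m)
    dX0[cbind(cache$amax0, seq_len(m))] <-
      dX0[cbind(cache$amax0, seq_len(m))] + df_g[m + seq_len(m)]
  } else {
    d <- config$hidden_dim
    K <- cache$n_units
    dH_next <- NULL   # grad wrt H2 of unit k (from unit k+1's input)
    dS_next <- NULL   # grad wrt S of unit k
    for (k in rev(seq_len(K))) {
      uc <- cache$units[[k]]
      n2 <- nrow(uc$H2)
      dH2 <- if (is.null(dH_next)) matrix(0, n2, d) else dH_next
      dS <- if (is.null(dS_next)) matrix(0, n2, n2) else dS_next
      # readout: every unit receives the same df_g
      dH2 <- dH2 + matrix(rep(df_g[seq_len(d)] / n2, each = n2), n2, d)
      dH2[cbind(uc$amax, seq_len(d))] <-
        dH2[cbind(uc$amax, seq_len(d))] + df_g[d + seq_len(d)]
      # structure learning
      dE <- row_sparsemax_bwd(dS, uc$S)
      dQ <- dE * uc$G * (1 - uc$G)
      dA2 <- config$lambda * dE
      dusl <- rowSums(dQ); dvsl <- colSums(dQ)
      a <- g(paste0("u", k, "_a"))
      a1 <- a[seq_len(d)]; a2 <- a[d + seq_len(d)]
      acc(paste0("u", k, "_a"),
          c(as.vector(crossprod(uc$H2, dusl)), as.vector(crossprod(uc$H2, dvsl))))
      dH2 <- dH2 + tcrossprod(dusl, a1) + tcrossprod(dvsl, a2)
      # pooling
      n_in <- nrow(uc$H1)
      dH1 <- matrix(0, n_in, d)
      dH1[uc$idx, ] <- dH2
      dA_in <- matrix(0, n_in, n_in)
      dA_in[uc$idx, uc$idx] <- dA2
      # convolution
      dZ <- dH1 * (uc$Z > 0)
      dM <- crossprod(uc$N, dZ)
      acc(paste0("u", k, "_W"), crossprod(uc$H_in, dM))
      W <- g(paste0("u", k, "_W"))
      dH_in <- tcrossprod(dM, W)
      if (k > 1) {
        # A entering this unit is the previous unit's S: push gradient
        # through the self-loop renormalization
        dN <- tcrossprod(dZ, uc$M)
        P <- dN * uc$N
        ddeg <- -(rowSums(P) + colSums(P)) / (2 * uc$deg)
        dA_hat <- dN * outer(uc$dinv, uc$dinv) + matrix(ddeg, n_in, n_in)
        dS_next <- dA_in + dA_hat
        dH_next <- dH_in
      } else {
        dX0 <- dX0 + dH_in
      }
    }
  }
  # node attention
  alpha <- cache$alpha; Tm <- cache$Tm
  dalpha <- as.vector(X0 %*% df_b)
  dX0 <- dX0 + tcrossprod(alpha, df_b)
  du <- alpha * (dalpha - sum(alpha * dalpha))
  acc("att_v", as.vector(crossprod(Tm, du)))
  dPre <- tcrossprod(du, g("att_v")) * (1 - Tm^2)
  acc("att_W", crossprod(X0, dPre))
  acc("att_b", .colSums(dPre, nrow(dPre), ncol(dPre)))
  dX0 <- dX0 + tcrossprod(dPre, g("att_W"))
  # reduction step
  if (cache$use_sage) {
    dZ0 <- dX0 * (cache$Z0 > 0)
    acc("sage_W", crossprod(cache$Hcat, dZ0))
    acc("sage_b", .colSums(dZ0, nrow(dZ0), ncol(dZ0)))
  }
  invisible(NULL)
}

# Gradient of the cross-entropy loss for one forwarded sample. `y` is 1 for
# the positive (depressed) class, 0 otherwise; class order is (HC, MDD).
model_backward <- function(fw, y, params, config, pre, gr) {
  target <- if (y == 1) c(0, 1) else c(1, 0)
  dlogits <- fw$prob - target
  gr$clf_W <- gr$clf_W + tcrossprod(dlogits, fw$z)
  gr$clf_b <- gr$clf_b + dlogits
  dz <- drop(crossprod(params$clf_W, dlogits))
  len_e <- length(fw$e$f_emb)
  dge <- dz[seq_len(len_e)]; dga <- dz[-seq_len(len_e)]
  df_e <- dge * fw$sw_e
  gr$e_gate <- gr$e_gate + dge * fw$e$f_emb * fw$sw_e * (1 - fw$sw_e)
  df_a <- dga * fw$sw_a
  gr$a_gate <- gr$a_gate + dga * fw$a$f_emb * fw$sw_a * (1 - fw$sw_a)
  bwd_modality(df_e, fw$e, params, "e", config, pre$eeg, gr)
  bwd_modality(df_a, fw$a, params, "a", config, pre$audio, gr)
  invisible(NULL)
}

zero_grads <- function(params) {
  gr <- new.env(parent = emptyenv())
  for (nm in names(params)) gr[[nm]] <- params[[nm]] * 0
  gr
}

# ---- training ---------------------------------------------------------------

# Precompute the operators shared by every sample, plus standardization.
build_pre <- function(dataset, config, train_idx) {
  samples <- dataset$samples
  ne <- nrow(samples[[1]]$eeg)
  std <- NULL
  if (config$standardize) {
    ne_me <- length(samples[[1]]$eeg)
    eeg_stack <- vapply(train_idx, function(i) as.vector(samples[[i]]$eeg),
                        numeric(ne_me))
    mu_v <- .rowMeans(eeg_stack, ne_me, length(train_idx))
    sd_v <- sqrt(.rowSums((eeg_stack - mu_v)^2, ne_me, length(train_idx)) /
                   max(length(train_idx) - 1, 1))
    mu_e <- matrix(mu_v, nrow(samples[[1]]$eeg))
    sd_e <- matrix(sd_v, nrow(samples[[1]]$eeg))
    sd_e[sd_e < 1e-8] <- 1
    a_cols <- ncol(samples[[1]]$audio)
    a_sum <- rep(0, a_cols); a_sq <- rep(0, a_cols); a_n <- 0
    for (i in train_idx) {
      a_sum <- a_sum + colSums(samples[[i]]$audio)
      a_sq <- a_sq + colSums(samples[[i]]$audio^2)
      a_n <- a_n + nrow(samples[[i]]$audio)
    }
    mu_a <- a_sum / a_n
    sd_a <- sqrt(pmax(a_sq / a_n - mu_a^2, 0))
    sd_a[sd_a < 1e-8] <- 1
    std <- list(mu_e = mu_e, sd_e = sd_e, mu_a = mu_a, sd_a = sd_a)
  }
  NM <- neighbor_mean_operator(dataset$A_eeg)
  pre <- list(eeg = list(N0 = gcn_norm_operator(dataset$A_eeg),
                         A0 = dataset$A_eeg, NM = NM, NM0 = NM),
              audio = list(N0 = gcn_norm_operator(dataset$A_audio),
                           A0 = dataset$A_audio,
                           NM0 = neighbor_mean_operator(dataset$A_audio)),
              std = std)
  pre
}

std_sample <- function(sample, std) {
  if (is.null(std)) {
    return(list(eeg = sample$eeg, audio = sample$audio))
  }
  n <- nrow(sample$audio)
  list(eeg = (sample$eeg - std$mu_e) / std$sd_e,
       audio = (sample$audio - rep(std$mu_a, each = n)) *
         rep(1 / std$sd_a, each = n))
}

#' Train the multimodal graph classifier
#'
#' Minibatch Adam on the softmax cross-entropy, with all gradients derived
#' analytically through the fusion head, the graph units (including sparsemax
#' structure learning and the degree renormalization of learned adjacencies)
#' and the neighbour-aggregation reduction. Pooling index selection is treated
#' as non-differentiable, as usual for top-k pooling. Training stops early
#' once the epoch-mean loss plateaus.
#'
#' @param dataset an `mdd_fixture` (or compatible list with `samples`,
#'   `A_eeg`, `A_audio`, `acoustic_manifest`).
#' @param config a [model_config()].
#' @param seed seed controlling initialization and minibatch shuffling.
#' @param indices training sample indices (default: all samples).
#' @param compute_attention average the channel attention over the training
#'   samples after the final epoch (one extra forward pass over the data);
#'   disable when only predictions are needed.
#' @return List of class `mdd_model` with `params`, `config`, `std`,
#'   `history` (per-epoch mean loss) and `attention` (dataset-averaged channel
#'   attention and audio feature-family gates).
#' @export
train_model <- function(dataset, config = model_config(), seed = 1,
                        indices = NULL, compute_attention = TRUE) {
  samples <- dataset$samples
  if (is.null(indices)) indices <- seq_along(samples)
  y <- vapply(samples, function(s) as.integer(s$label == "MDD"), 1L)[indices]
  pre <- build_pre(dataset, config, indices)
  m_e <- ncol(samples[[1]]$eeg); m_a <- ncol(samples[[1]]$audio)
  params <- init_params(config, m_e, m_a, seed = seed)
  # cache standardized inputs and the reduction's concatenated features once
  Xe <- vector("list", length(indices)); Xa <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    s <- std_sample(samples[[indices[j]]], pre$std)
    Xe[[j]] <- s$eeg; Xa[[j]] <- s$audio
  }
  Hcat <- lapply(Xe, function(X) cbind(X, pre$eeg$NM %*% X))

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  t_step <- 0
  history <- numeric(0)
  plateau <- 0
  set.seed(seed + 1)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(seq_along(indices))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
      gr <- zero_grads(params)
      for (j in batch) {
        pre_j <- pre
        pre_j$eeg$Hcat <- Hcat[[j]]
        fw <- model_forward(Xe[[j]], Xa[[j]], params, config, pre_j)
        ep_loss <- ep_loss - log(max(fw$prob[y[j] + 1L], 1e-12))
        model_backward(fw, y[j], params, config, pre_j, gr)
      }
      t_step <- t_step + 1
      scale <- 1 / length(batch)
      for (nm in names(params)) {
        gnm <- gr[[nm]] * scale
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gnm
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gnm^2
        mhat <- adam_m[[nm]] / (1 - b1^t_step)
        vhat <- adam_v[[nm]] / (1 - b2^t_step)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + aeps)
      }
    }
    ep_loss <- ep_loss / length(ord)
    if (length(history) > 0) {
      rel <- (history[length(history)] - ep_loss) /
        max(abs(history[length(history)]), 1e-12)
      plateau <- if (rel < config$early_stop_tol) plateau + 1 else 0
    }
    history <- c(history, ep_loss)
    if (plateau >= config$patience) break
  }

  # dataset-averaged channel attention and the audio feature-level gate
  attention <- NULL
  if (compute_attention) {
    alpha_sum <- 0
    for (j in seq_along(indices)) {
      pre_j <- pre
      pre_j$eeg$Hcat <- Hcat[[j]]
      fw <- model_forward(Xe[[j]], Xa[[j]], params, config, pre_j)
      alpha_sum <- alpha_sum + fw$e$alpha
    }
    attention <- list(channel = alpha_sum / length(indices),
                      channel_labels = rownames(samples[[1]]$eeg),
                      audio_gate = sigmoid(params$a_gate[seq_len(m_a)]))
  }

  structure(list(params = params, config = config, std = pre$std,
                 pre = pre[c("eeg", "audio")], history = history,
                 attention = attention, seed = seed),
            class = "mdd_model")
}

#' Class probabilities for samples
#'
#' @param model an [train_model()] result.
#' @param dataset the dataset holding the samples (same graph layout as the
#'   training data).
#' @param indices which samples to score (default: all).
#' @return Matrix with columns `HC`, `MDD`; rows sum to 1.
#' @export
predict_model <- function(model, dataset, indices = NULL) {
  if (is.null(indices)) indices <- seq_along(dataset$samples)
  out <- matrix(NA_real_, length(indices), 2,
                dimnames = list(NULL, c("HC", "MDD")))
  pre <- model$pre
  pre$std <- model$std
  for (j in seq_along(indices)) {
    s <- std_sample(dataset$samples[[indices[j]]], model$std)
    fw <- model_forward(s$eeg, s$audio, model$params, model$config, pre)
    out[j, ] <- fw$prob
  }
  out
}

#' Save / load a trained model
#'
#' Serializes every parameter tensor together with a manifest (tensor shapes,
#' configuration, training seed, standardization statistics) into one JSON
#' archive, so a trained model can be inspected or reloaded without any
#' binary format.
#'
#' @param model an [train_model()] result.
#' @param path output file (JSON).
#' @return `read_model()` returns the restored `mdd_model` (its graph
#'   operators are rebuilt from the stored adjacencies).
#' @export
write_model <- function(model, path) {
  arch <- list(
    manifest = list(
      config = unclass(model$config),
      seed = model$seed,
      shapes = lapply(model$params, function(p) if (is.matrix(p)) dim(p) else length(p)),
      epochs_trained = length(model$history)),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    }),
    std = model$std,
    history = model$history,
    attention = model$attention,
    A_eeg = model$pre$eeg$A0,
    A_audio = model$pre$audio$A0)
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, arch$manifest$config[names(formals(model_config))])
  params <- lapply(arch$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  std <- arch$std
  if (!is.null(std)) {
    std$mu_e <- as.matrix(std$mu_e); std$sd_e <- as.matrix(std$sd_e)
  }
  A_eeg <- as.matrix(arch$A_eeg); A_audio <- as.matrix(arch$A_audio)
  NM <- neighbor_mean_operator(A_eeg)
  attention <- arch$attention
  structure(list(params = params, config = cfg, std = std,
                 pre = list(eeg = list(N0 = gcn_norm_operator(A_eeg),
                                       A0 = A_eeg, NM = NM, NM0 = NM),
                            audio = list(N0 = gcn_norm_operator(A_audio),
                                         A0 = A_audio,
                                         NM0 = neighbor_mean_operator(A_audio))),
                 history = arch$history, attention = attention,
                 seed = arch$manifest$seed),
            class = "mdd_model")
}

#' @export
print.mdd_model <- function(x, ...) {
  cat(sprintf("Multimodal graph classifier: %d+%d units, %d epochs trained (final loss %.4f)\n",
              x$config$eeg_units, x$config$audio_units,
              length(x$history), x$history[length(x$history)]))
  invisible(x)
}
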