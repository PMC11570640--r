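#' Initialize node-attention parameters
#'
#' @param m feature dimension of the initial graph feature matrix.
#' @param h attention hidden width.
#' @return List with `W` (`m x h`), `b` (length `h`) and `v` (length `h`).
#' @export
node_attention_params <- function(m, h = 16) {
  list(W = matrix(stats::rnorm(m * h, sd = sqrt(2 / m)), m, h),
       b = rep(0, h),
       v = stats::rnorm(h, sd = 0.1))
}

#' Channel / slice level attention over initial features
#'
#' Computes one logit per node as `v . tanh(W' x_i + b)`, a softmax over nodes,
#' and the attention-weighted context vector `f_b = sum_i alpha_i x_i`. For EEG
#' the nodes are electrode channels; for audio they are time slices.
#'
#' @param X0 `n x m` initial node feature matrix.
#' @param params list with `W` (`m x h`), `b`, `v`, e.g. from
#'   [node_attention_params()].
#' @return List with `alpha` (length `n`, positive, sums to 1) and `f_b`
#'   (length `m`).
#' @export
node_attention <- function(X0, params) {
  check_finite_matrix(X0, "X0")
  stop_if(ncol(X0) != nrow(params$W), "X0 columns must match attention weight rows",
          "mdgraph_shape_error")
  Tm <- tanh(sweep(X0 %*% params$W, 2, params$b, "+"))   # n x h
  u <- drop(Tm %*% params$v)
  alpha <- softmax_vec(u)
  list(alpha = alpha, f_b = drop(crossprod(X0, alpha)))
}

#' Assemble a modality embedding
#'
#' Fixed-order concatenation of the attention context vector `f_b` and the
#' graph embedding `f_g` (`f_b` first).
#'
#' @param f_b context vector from [node_attention()].
#' @param f_g graph embedding from [multi_gcn_forward()].
#' @return List of class `modality_embedding` with `f_b`, `f_g` and
#'   `f_embedding = c(f_b, f_g)`.
#' @export
assemble_embedding <- function(f_b, f_g) {
  stop_if(any(!is.finite(f_b)) || any(!is.finite(f_g)),
          "embedding parts must be finite")
  structure(list(f_b = f_b, f_g = f_g, f_embedding = c(f_b, f_g)),
            class = "modality_embedding")
}

#' Feature-level modality attention gate
#'
#' Hadamard product of the embedding with `sigmoid(w)`: every coordinate is
#' shrunk towards zero by its learned gate, never amplified and never
#' sign-flipped.
#'
#' @param embedding a [assemble_embedding()] result or plain numeric vector.
#' @param w gate vector, same length as the embedding.
#' @return Gated numeric vector.
#' @export
modality_attention <- function(embedding, w) {
  f <- if (inherits(embedding, "modality_embedding")) embedding$f_embedding else embedding
  stop_if(length(f) != length(w), "gate length must match embedding length",
          "mdgraph_shape_error")
  f * sigmoid(w)
}

#' Fuse gated modality embeddings and classify
#'
#' Concatenates the gated EEG and audio embeddings and applies one affine
#' layer with a softmax over the `C` classes.
#'
#' @param e_embed,a_embed modality embeddings ([assemble_embedding()] or
#'   numeric vectors).
#' @param params list with gates `w_e`, `w_a`, affine `W` (`C x (len_e+len_a)`)
#'   and bias `b` (length `C`).
#' @return List with `prob` (length `C`, sums to 1), `logits` and the fused
#'   gated vector `z`.
#' @export
fuse_and_classify <- function(e_embed, a_embed, params) {
  ge <- modality_attention(e_embed, params$w_e)
  ga <- modality_attention(a_embed, params$w_a)
  z <- c(ge, ga)
  stop_if(any(!is.finite(z)), "NaN/Inf in fused embeddings", "mdgraph_validation_error")
  logits <- drop(params$W %*% z + params$b)
  list(prob = softmax_vec(logits), logits = logits, z = z)
}

#' Export per-channel and per-feature-family attention scores
#'
#' Reports the EEG channel-level attention scores (one per electrode) and the
#' audio feature-family attention (the sigmoid gate values of the audio
#' embedding's `f_b` block, averaged within each family's column span of the
#' acoustic manifest). Each table also carries the baseline-subtracted score
#' (minimum score subtracted), the convention used for attention rankings.
#'
#' @param alpha_channels numeric vector of channel attention scores (e.g.
#'   dataset-averaged `alpha` from [node_attention()]).
#' @param channel_labels channel labels, same length.
#' @param audio_gate sigmoid gate values over the audio `f_b` block (length =
#'   number of audio feature columns), or `NULL` to skip the family table.
#' @param manifest acoustic [feature_manifest()] mapping columns to families.
#' @return List of two data frames: `channels` with
#'   `channel_label, score, baseline_subtracted` and `features` with
#'   `feature_family, score, baseline_subtracted`.
#' @export
export_attention <- function(alpha_channels, channel_labels,
                             audio_gate = NULL, manifest = NULL) {
  stop_if(length(alpha_channels) != length(channel_labels),
          "channel scores and labels differ in length", "mdgraph_shape_error")
  channels <- data.frame(channel_label = as.character(channel_labels),
                         score = as.numeric(alpha_channels),
                         baseline_subtracted = as.numeric(alpha_channels) - min(alpha_channels),
                         stringsAsFactors = FALSE)
  features <- NULL
  if (!is.null(audio_gate)) {
    stop_if(is.null(manifest), "manifest required to aggregate feature families")
    stop_if(length(audio_gate) != nrow(manifest),
            "audio gate length must match manifest rows", "mdgraph_shape_error")
    fam_levels <- unique(manifest$family)
    sc <- vapply(fam_levels, function(f) mean(audio_gate[manifest$family == f]),
                 numeric(1))
    features <- data.frame(feature_family = fam_levels,
                           score = as.numeric(sc),
                           baseline_subtracted = as.numeric(sc) - min(sc),
                           stringsAsFactors = FALSE)
  }
  list(channels = channels, features = features)
}

#' Write an attention report to CSV
#'
#' @param report result of [export_attention()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_attention_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "channel_attention.csv")
  utils::write.csv(report$channels, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$features)) {
    p <- file.path(dir, "feature_family_attention.csv")
    utils::write.csv(report$features, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
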