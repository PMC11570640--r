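# Shared builders for small in-code fixtures.

tiny_montage <- function() {
  # 3 mirrored pairs: frontal, central, posterior; no midline
  electrode_montage(
    labels = c("L1", "R1", "L2", "R2", "L3", "R3"),
    coords = rbind(c(-0.5, 0.8), c(0.5, 0.8),
                   c(-0.8, 0.0), c(0.8, 0.0),
                   c(-0.5, -0.8), c(0.5, -0.8)),
    hemisphere = c("left", "right", "left", "right", "left", "right"))
}

random_montage <- function(n, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  x <- runif(half, 0.1, 1); y <- runif(half, -1, 1)
  electrode_montage(
    labels = c(sprintf("L%02d", seq_len(half)), sprintf("R%02d", seq_len(half)),
               if (n %% 2 == 1) "Z1"),
    coords = rbind(cbind(-x, y), cbind(x, y),
                   if (n %% 2 == 1) c(0, 0)),
    hemisphere = c(rep("left", half), rep("right", half),
                   if (n %% 2 == 1) "midline"))
}

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

tiny_fixture <- function(seed = 7, effect_size = 1, n_channels = 12,
                         n_slices = 6, segs = 3, mdd = 2, hc = 2) {
  generate_dataset(fixture_config(
    n_mdd_subjects = mdd, n_hc_subjects = hc, segments_per_subject = segs,
    n_eeg_channels = n_channels, n_audio_slices = n_slices, m_e = 4,
    effect_size = effect_size, seed = seed))
}

tiny_model_config <- function(...) {
  args <- utils::modifyList(list(m_prime_e = 8, hidden_dim = 4, att_dim = 4,
                                 epochs = 3, batch_size = 4, lr = 1e-2),
                            list(...))
  do.call(model_config, args)
}

sine_recording <- function(freq = 440, rate = 44100, dur = 0.2, amp = 1) {
  audio_recording(amp * sin(2 * pi * freq * seq_len(round(rate * dur)) / rate),
                  rate)
}
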