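#' Audio recording container
#'
#' @param samples numeric vector of mono amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate) {
  stop_if(!is.numeric(samples) || length(samples) < 1, "samples must be non-empty numeric")
  stop_if(!is.numeric(rate) || length(rate) != 1 || rate <= 0, "rate must be positive")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("Audio recording: %d samples at %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Acoustic feature configuration
#'
#' Controls the framing and the per-family layout of the slice feature vector.
#' The default layout concatenates, in this fixed order, the frame-averaged
#' mean and standard deviation of: 64 MFCCs plus their deltas (256 columns),
#' 128 log-mel band energies (256), pitch (2), RMS energy (2), 12 chroma bins
#' (24), 7 spectral-contrast bands as peak-valley contrast plus valley level
#' (28) and the 6 tonnetz dimensions (12) - 580 columns in total. The layout is
#' recorded by [feature_manifest()].
#'
#' @param n_fft analysis frame length in samples.
#' @param hop hop length between frames in samples.
#' @param n_mels number of mel filterbank bands.
#' @param n_mfcc number of cepstral coefficients retained.
#' @param n_contrast_bands number of octave bands for spectral contrast.
#' @param contrast_fmin lower edge (Hz) of the first octave band.
#' @param contrast_quantile fraction of band bins treated as peak/valley.
#' @param pitch_fmin,pitch_fmax pitch search range in Hz.
#' @param voicing_threshold normalized-autocorrelation threshold below which a
#'   frame is unvoiced (pitch sentinel 0).
#' @return A list of class `acoustic_config`.
#' @export
acoustic_config <- function(n_fft = 2048, hop = 512, n_mels = 128, n_mfcc = 64,
                            n_contrast_bands = 7, contrast_fmin = 200,
                            contrast_quantile = 0.2,
                            pitch_fmin = 50, pitch_fmax = 600,
                            voicing_threshold = 0.3) {
  structure(list(n_fft = n_fft, hop = hop, n_mels = n_mels, n_mfcc = n_mfcc,
                 n_contrast_bands = n_contrast_bands,
                 contrast_fmin = contrast_fmin,
                 contrast_quantile = contrast_quantile,
                 pitch_fmin = pitch_fmin, pitch_fmax = pitch_fmax,
                 voicing_threshold = voicing_threshold),
            class = "acoustic_config")
}

#' Feature-family manifest
#'
#' Enumerates every column of the slice feature vector with its family tag, in
#' emission order. Per-family counts sum exactly to the configured feature
#' dimension; the manifest is what downstream attention export uses to map
#' feature-level gates back to the seven acoustic families.
#'
#' @param config an [acoustic_config()].
#' @return Data frame with columns `index`, `family`, `name`.
#' @export
feature_manifest <- function(config = acoustic_config()) {
  nm <- character(0); fam <- character(0)
  add <- function(family, names) {
    fam <<- c(fam, rep(family, length(names))); nm <<- c(nm, names)
  }
  stats2 <- function(base) as.vector(rbind(paste0(base, "_mean"), paste0(base, "_sd")))
  add("mfcc", stats2(paste0("mfcc", seq_len(config$n_mfcc))))
  add("mfcc", stats2(paste0("dmfcc", seq_len(config$n_mfcc))))
  add("mel", stats2(paste0("mel", seq_len(config$n_mels))))
  add("pitch", c("pitch_mean", "pitch_sd"))
  add("energy", c("rms_mean", "rms_sd"))
  add("chroma", stats2(paste0("chroma", seq_len(12))))
  add("contrast", stats2(paste0("contrast", seq_len(config$n_contrast_bands))))
  add("contrast", stats2(paste0("valley", seq_len(config$n_contrast_bands))))
  add("tonnetz", stats2(paste0("tonnetz", seq_len(6))))
  data.frame(index = seq_along(nm), family = fam, name = nm,
             stringsAsFactors = FALSE)
}

#' Cut a recording into equal-duration slices
#'
#' Each of the `n_slices` slices holds `floor(L / n_slices)` samples; trailing
#' remainder samples are discarded (not padded) so every slice is statistically
#' comparable.
#'
#' @param recording an [audio_recording()].
#' @param n_slices number of slices (chain-graph nodes).
#' @return List of `n_slices` [audio_recording()] objects.
#' @export
slice_waveform <- function(recording, n_slices) {
  stop_if(!inherits(recording, "audio_recording"), "recording must be an audio_recording")
  stop_if(n_slices < 1 || n_slices != round(n_slices), "n_slices must be a positive integer",
          "mdgraph_parameter_error")
  L <- length(recording$samples)
  stop_if(L < n_slices, sprintf("recording too short: %d samples for %d slices", L, n_slices),
          "mdgraph_input_error")
  w <- L %/% n_slices
  lapply(seq_len(n_slices), function(i) {
    audio_recording(recording$samples[((i - 1) * w + 1):(i * w)], recording$rate)
  })
}

# ---- spectral internals -----------------------------------------------------

# Frame a signal into columns; zero-pads to one frame when shorter than n_fft.
frame_signal <- function(x, n_fft, hop) {
  L <- length(x)
  if (L < n_fft) {
    return(matrix(c(x, rep(0, n_fft - L)), ncol = 1))
  }
  starts <- seq(1, L - n_fft + 1, by = hop)
  vapply(starts, function(s) x[s:(s + n_fft - 1)], numeric(n_fft))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Power spectrogram: (n_fft/2 + 1) x n_frames.
stft_power <- function(x, n_fft, hop) {
  fr <- frame_signal(x, n_fft, hop)
  w <- hann_window(n_fft)
  sp <- stats::mvfft(fr * w)
  Mod(sp[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2
}

# HTK mel scale filterbank: n_mels x n_bins triangular filters.
mel_filterbank <- function(rate, n_fft, n_mels, fmin = 0, fmax = rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2 + 1
  bin_freq <- (seq_len(n_bins) - 1) * rate / n_fft
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- fpts[m]; ce <- fpts[m + 1]; hi <- fpts[m + 2]
    up <- (bin_freq - lo) / (ce - lo)
    dn <- (hi - bin_freq) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), as used for cepstra.
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  m <- seq_len(n_in) - 0.5
  C <- sqrt(2 / n_in) * cos(pi * outer(k, m) / n_in)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

# Autocorrelation pitch per frame; 0 marks unvoiced frames.
pitch_track <- function(frames, rate, fmin, fmax, threshold) {
  n <- nrow(frames)
  lag_min <- max(2, floor(rate / fmax))
  lag_max <- min(n - 1, ceiling(rate / fmin))
  apply(frames, 2, function(fr) {
    if (lag_max <= lag_min) return(0)
    pad <- c(fr, rep(0, n))
    ac <- Re(stats::fft(Mod(stats::fft(pad))^2, inverse = TRUE)) / length(pad)
    if (ac[1] <= 0) return(0)
    seg <- ac[(lag_min + 1):(lag_max + 1)]
    pk <- which.max(seg)
    if (seg[pk] / ac[1] < threshold) return(0)
    rate / (lag_min + pk - 1)
  })
}

chroma_map <- function(rate, n_fft) {
  n_bins <- n_fft %/% 2 + 1
  f <- (seq_len(n_bins) - 1) * rate / n_fft
  pc <- rep(NA_integer_, n_bins)
  ok <- f >= 27.5
  pc[ok] <- (round(12 * log2(f[ok] / 440)) %% 12) + 1
  pc
}

# 6 x 12 tonal-centroid projection: circles of fifths, minor and major thirds.
tonnetz_basis <- function() {
  j <- 0:11
  rbind(sin(j * 7 * pi / 6), cos(j * 7 * pi / 6),
        sin(j * 3 * pi / 2), cos(j * 3 * pi / 2),
        0.5 * sin(j * 2 * pi / 3), 0.5 * cos(j * 2 * pi / 3))
}

mean_sd_cols <- function(M) {
  # interleaved per-row (mean, sd) over frames; single frame gives sd 0
  mu <- rowMeans(M)
  sd <- if (ncol(M) > 1) apply(M, 1, stats::sd) else rep(0, nrow(M))
  as.vector(rbind(mu, sd))
}

#' Emotion-feature row for one audio slice
#'
#' Computes frame-level MFCC (+deltas), log-mel band energies, pitch, RMS
#' energy, chroma, spectral contrast and tonnetz, then aggregates each over
#' frames as mean and standard deviation, concatenated in the fixed order of
#' [feature_manifest()]. Silent input yields defined values everywhere: RMS 0,
#' pitch 0 (unvoiced sentinel), zero chroma/tonnetz - never `NaN`.
#'
#' @param slice an [audio_recording()] (one slice).
#' @param config an [acoustic_config()].
#' @return Named numeric vector whose length equals `nrow(feature_manifest(config))`.
#' @export
compute_slice_features <- function(slice, config = acoustic_config()) {
  stop_if(!inherits(slice, "audio_recording"), "slice must be an audio_recording")
  x <- slice$samples
  rate <- slice$rate
  eps <- 1e-10
  fr <- frame_signal(x, config$n_fft, config$hop)
  P <- stft_power(x, config$n_fft, config$hop)        # bins x frames
  nF <- ncol(P)

  fb <- mel_filterbank(rate, config$n_fft, config$n_mels)
  logmel <- log(fb %*% P + eps)                        # n_mels x frames
  C <- dct_matrix(config$n_mfcc, config$n_mels)
  mfcc <- C %*% logmel                                 # n_mfcc x frames
  dmfcc <- if (nF > 1) cbind(0, t(diff(t(mfcc)))) else matrix(0, config$n_mfcc, 1)

  pitch <- pitch_track(fr, rate, config$pitch_fmin, config$pitch_fmax,
                       config$voicing_threshold)
  voiced <- pitch[pitch > 0]
  pitch_stats <- c(if (length(voiced) > 0) mean(voiced) else 0,
                   if (length(voiced) > 1) stats::sd(voiced) else 0)

  rms <- sqrt(colMeans(fr^2))
  rms_stats <- c(mean(rms), if (nF > 1) stats::sd(rms) else 0)

  pc <- chroma_map(rate, config$n_fft)
  chroma <- matrix(0, 12, nF)
  ok <- !is.na(pc)
  for (f in seq_len(nF)) {
    v <- rep(0, 12)
    cs <- tapply(P[ok, f], pc[ok], sum)
    v[as.integer(names(cs))] <- cs
    tot <- sum(v)
    chroma[, f] <- if (tot > eps) v / tot else rep(0, 12)
  }
  tonnetz <- tonnetz_basis() %*% chroma                # 6 x frames

  nb <- config$n_contrast_bands
  n_bins <- nrow(P)
  bin_freq <- (seq_len(n_bins) - 1) * rate / config$n_fft
  edges <- c(0, config$contrast_fmin * 2^(0:(nb - 2)), rate / 2 + 1)
  contrast <- matrix(0, nb, nF); valley <- matrix(0, nb, nF)
  for (b in seq_len(nb)) {
    sel <- which(bin_freq >= edges[b] & bin_freq < edges[b + 1])
    if (length(sel) == 0) next
    q <- max(1, ceiling(config$contrast_quantile * length(sel)))
    for (f in seq_len(nF)) {
      s <- sort(P[sel, f])
      pk <- mean(s[(length(s) - q + 1):length(s)])
      vl <- mean(s[seq_len(q)])
      contrast[b, f] <- log(pk + eps) - log(vl + eps)
      valley[b, f] <- log(vl + eps)
    }
  }

  out <- c(mean_sd_cols(mfcc), mean_sd_cols(dmfcc), mean_sd_cols(logmel),
           pitch_stats, rms_stats, mean_sd_cols(chroma),
           mean_sd_cols(contrast), mean_sd_cols(valley), mean_sd_cols(tonnetz))
  man <- feature_manifest(config)
  stop_if(length(out) != nrow(man), "feature layout / manifest length mismatch")
  stats::setNames(out, man$name)
}

#' Initial audio graph feature matrix
#'
#' Slices the recording into `n_slices` equal-duration segments and stacks one
#' [compute_slice_features()] row per slice, in time order, so that node `i` of
#' the chain graph is slice `i`.
#'
#' @param recording an [audio_recording()].
#' @param n_slices number of slices (default 32).
#' @param config an [acoustic_config()].
#' @return `n_slices x m` numeric matrix with manifest column names; attribute
#'   `"manifest"` holds the [feature_manifest()].
#' @export
build_audio_feature_matrix <- function(recording, n_slices = 32,
                                       config = acoustic_config()) {
  slices <- slice_waveform(recording, n_slices)
  rows <- lapply(slices, compute_slice_features, config = config)
  X <- do.call(rbind, rows)
  rownames(X) <- paste0("slice", seq_len(n_slices))
  attr(X, "manifest") <- feature_manifest(config)
  X
}

# ---- minimal PCM WAV i/o ----------------------------------------------------

#' Read / write 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE codec for fixtures and the command-line feature extractor:
#' 16-bit PCM only; multichannel input is averaged to mono on read.
#'
#' @param path file path.
#' @return `read_wav()` returns an [audio_recording()] with amplitudes in
#'   `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stop_if(riff != "RIFF", "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  stop_if(readChar(con, 4, useBytes = TRUE) != "WAVE", "not a WAVE file")
  rate <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      stop_if(fmt[1] != 1, "only PCM WAV is supported")
      n_channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      stop_if(bits != 16, "only 16-bit PCM is supported")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      data <- readBin(con, "integer", size / 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  stop_if(is.null(rate) || is.null(data), "malformed WAV file")
  x <- data / 32768
  if (n_channels > 1) {
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  audio_recording(x, rate)
}

#' @rdname read_wav
#' @param recording the [audio_recording()] to write (amplitudes clipped to
#'   `[-1, 1]`).
#' @export
write_wav <- function(recording, path) {
  x <- pmin(1, pmax(-1, recording$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")
  writeBin(as.integer(recording$rate), con, size = 4, endian = "little")
  writeBin(as.integer(recording$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
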