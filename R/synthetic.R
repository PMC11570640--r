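#' Synthetic montage on concentric rings
#'
#' Places electrodes on concentric rings of the unit disk, mirrored across the
#' vertical midline: channels come in left/right pairs at `(-x, y)` / `(x, y)`
#' (labels `L***` / `R***`), with a single midline channel `Z001` at the origin
#' when the channel count is odd. Anterior is positive `y`. The construction is
#' deterministic: regenerating with the same `n` gives an identical montage.
#' It stands in for a real high-density net layout, which is not redistributed
#' here; positions are synthetic.
#'
#' @param n_channels total channel count (>= 2).
#' @param pairs_per_ring how many mirrored pairs share one ring radius.
#' @return An [electrode_montage()] with rows ordered `L001, R001, L002, ...`.
#' @export
generate_montage <- function(n_channels, pairs_per_ring = 8) {
  stop_if(n_channels < 2, "need at least 2 channels", "mdgraph_parameter_error")
  n_pairs <- n_channels %/% 2
  n_mid <- n_channels - 2 * n_pairs
  n_rings <- ceiling(n_pairs / pairs_per_ring)
  labels <- character(0); xs <- numeric(0); ys <- numeric(0); hemi <- character(0)
  for (i in seq_len(n_pairs)) {
    ring <- ceiling(i / pairs_per_ring)
    in_ring <- min(pairs_per_ring, n_pairs - (ring - 1) * pairs_per_ring)
    pos <- i - (ring - 1) * pairs_per_ring
    r <- ring / n_rings
    # angle from the anterior (+y) axis, kept off the midline
    phi <- if (in_ring == 1) pi / 2 else (15 + (pos - 1) * 150 / (in_ring - 1)) * pi / 180
    x <- r * sin(phi); y <- r * cos(phi)
    labels <- c(labels, sprintf("L%03d", i), sprintf("R%03d", i))
    xs <- c(xs, -x, x); ys <- c(ys, y, y)
    hemi <- c(hemi, "left", "right")
  }
  if (n_mid == 1) {
    labels <- c(labels, "Z001"); xs <- c(xs, 0); ys <- c(ys, 0)
    hemi <- c(hemi, "midline")
  }
  electrode_montage(labels, cbind(xs, ys), hemi)
}

#' Fixture configuration
#'
#' Defaults reproduce the layout of a paired EEG/audio depression study:
#' 22 depressed and 29 control subjects, 29 paired segments each (so
#' `22 * 29 = 638` positive and `29 * 29 = 841` control samples), 128 EEG
#' channels and 32 audio slices per sample.
#'
#' @param n_mdd_subjects,n_hc_subjects subject counts per class.
#' @param segments_per_subject paired segments per subject.
#' @param n_eeg_channels EEG channel count.
#' @param n_audio_slices audio chain-graph nodes per sample.
#' @param m_e raw per-channel EEG feature dimension (band-power-like
#'   summaries; the downstream reduction is dimension-agnostic).
#' @param effect_size standardized mean shift of class-dependent features
#'   (units of `noise_sd`).
#' @param noise_sd per-entry observation noise standard deviation.
#' @param subject_sd standard deviation of the subject-level random effect
#'   shared across a subject's segments.
#' @param asym_frac fraction of `effect_size` added to left-hemisphere and
#'   removed from right-hemisphere signal channels in the depressed class
#'   (hemispheric asymmetry).
#' @param audio_format `"features"` emits slice-feature matrices directly in
#'   the acoustic manifest layout; `"waveform"` emits short synthetic
#'   tone-plus-noise recordings with class-shifted pitch and energy.
#' @param acoustic an [acoustic_config()] defining the audio feature layout.
#' @param wav_rate,wav_duration rate (Hz) and length (s) of synthetic
#'   waveforms when `audio_format = "waveform"`.
#' @param seed integer seed controlling every random draw.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_mdd_subjects = 22, n_hc_subjects = 29,
                           segments_per_subject = 29, n_eeg_channels = 128,
                           n_audio_slices = 32, m_e = 16,
                           effect_size = 1.0, noise_sd = 1.0,
                           subject_sd = 0.3, asym_frac = 0.5,
                           audio_format = c("features", "waveform"),
                           acoustic = acoustic_config(),
                           wav_rate = 8000, wav_duration = 1.0,
                           seed = 1) {
  audio_format <- match.arg(audio_format)
  cfg <- list(n_mdd_subjects = n_mdd_subjects, n_hc_subjects = n_hc_subjects,
              segments_per_subject = segments_per_subject,
              n_eeg_channels = n_eeg_channels, n_audio_slices = n_audio_slices,
              m_e = m_e, effect_size = effect_size, noise_sd = noise_sd,
              subject_sd = subject_sd, asym_frac = asym_frac,
              audio_format = audio_format, acoustic = acoustic,
              wav_rate = wav_rate, wav_duration = wav_duration, seed = seed)
  for (f in c("n_mdd_subjects", "n_hc_subjects", "segments_per_subject",
              "n_eeg_channels", "n_audio_slices", "m_e")) {
    stop_if(cfg[[f]] < 1, sprintf("%s must be >= 1", f), "mdgraph_parameter_error")
  }
  stop_if(effect_size < 0, "effect_size must be >= 0", "mdgraph_parameter_error")
  structure(cfg, class = "fixture_config")
}

# Channels designated as carrying the class signal: frontal (anterior ring
# positions) and temporal (far-lateral positions).
signal_channel_mask <- function(montage) {
  montage$y > 0.4 | abs(montage$x) > 0.75
}

#' Generate a paired EEG/audio fixture dataset
#'
#' Draws a fully seeded synthetic dataset with known class-dependent
#' structure. EEG samples are `channels x m_e` matrices of unit-variance noise
#' plus (i) a subject-level random effect per channel shared across that
#' subject's segments and (ii), for the depressed class, a mean shift of
#' `effect_size * noise_sd` on a designated frontal/temporal channel subset,
#' stronger on the left hemisphere and weaker on the right (hemispheric
#' asymmetry). Audio samples carry the class shift on the pitch and energy
#' feature families and (at half strength) on the mel band means, either
#' directly in the slice-feature matrix (`audio_format = "features"`) or as a
#' lowered fundamental frequency and reduced amplitude of a synthetic
#' tone-plus-noise waveform.
#'
#' @param config a [fixture_config()].
#' @return List of class `mdd_fixture` with elements `samples` (list; each has
#'   `subject_id`, `segment_id`, `label`, `eeg`, `audio`), `montage`, `pairs`,
#'   `A_eeg`, `A_audio`, `acoustic_manifest` and `manifest` (config echo, seed,
#'   signal channel labels, audio signal columns).
#' @export
generate_dataset <- function(config = fixture_config()) {
  stop_if(!inherits(config, "fixture_config"), "config must be a fixture_config")
  set.seed(config$seed)
  montage <- generate_montage(config$n_eeg_channels)
  pairs <- default_symmetric_pairs(montage)
  A_eeg <- combine_adjacency(build_local_adjacency(montage, k = 4),
                             build_symmetric_adjacency(montage, pairs))
  A_audio <- build_chain_adjacency(config$n_audio_slices)
  man <- feature_manifest(config$acoustic)

  sig <- signal_channel_mask(montage)
  sig_left <- sig & montage$hemisphere == "left"
  sig_right <- sig & montage$hemisphere == "right"
  eeg_shift <- rep(0, config$n_eeg_channels)
  delta <- config$effect_size * config$noise_sd
  eeg_shift[sig] <- delta
  eeg_shift[sig_left] <- delta * (1 + config$asym_frac)
  eeg_shift[sig_right] <- delta * (1 - config$asym_frac)

  audio_cols_full <- which(man$family %in% c("pitch", "energy"))
  audio_cols_half <- which(man$family == "mel" & grepl("_mean$", man$name))
  m_a <- nrow(man)
  audio_shift <- rep(0, m_a)
  audio_shift[audio_cols_full] <- delta
  audio_shift[audio_cols_half] <- delta / 2

  subjects <- data.frame(
    subject_id = c(sprintf("MDD%02d", seq_len(config$n_mdd_subjects)),
                   sprintf("HC%02d", seq_len(config$n_hc_subjects))),
    label = c(rep("MDD", config$n_mdd_subjects), rep("HC", config$n_hc_subjects)),
    stringsAsFactors = FALSE)

  samples <- vector("list", nrow(subjects) * config$segments_per_subject)
  s_i <- 0
  for (r in seq_len(nrow(subjects))) {
    subj_eeg <- stats::rnorm(config$n_eeg_channels, sd = config$subject_sd)
    subj_audio <- stats::rnorm(1, sd = config$subject_sd)
    is_mdd <- subjects$label[r] == "MDD"
    for (seg in seq_len(config$segments_per_subject)) {
      eeg <- matrix(stats::rnorm(config$n_eeg_channels * config$m_e,
                                 sd = config$noise_sd),
                    config$n_eeg_channels, config$m_e) + subj_eeg
      if (is_mdd) eeg <- eeg + eeg_shift
      rownames(eeg) <- montage$label

      if (config$audio_format == "features") {
        audio <- matrix(stats::rnorm(config$n_audio_slices * m_a,
                                     sd = config$noise_sd),
                        config$n_audio_slices, m_a) + subj_audio
        if (is_mdd) audio <- sweep(audio, 2, audio_shift, "+")
        colnames(audio) <- man$name
      } else {
        audio <- synth_waveform(config, is_mdd, subj_audio)
      }
      s_i <- s_i + 1
      samples[[s_i]] <- list(subject_id = subjects$subject_id[r],
                             segment_id = seg,
                             label = subjects$label[r],
                             eeg = eeg, audio = audio)
    }
  }

  manifest <- list(
    config = config, seed = config$seed,
    n_samples = length(samples),
    n_mdd_samples = config$n_mdd_subjects * config$segments_per_subject,
    n_hc_samples = config$n_hc_subjects * config$segments_per_subject,
    signal_channels = montage$label[sig],
    signal_channels_left = montage$label[sig_left],
    signal_channels_right = montage$label[sig_right],
    audio_signal_columns = sort(c(audio_cols_full, audio_cols_half)))
  structure(list(samples = samples, montage = montage, pairs = pairs,
                 A_eeg = A_eeg, A_audio = A_audio,
                 acoustic_manifest = man, manifest = manifest),
            class = "mdd_fixture")
}

# Tone-plus-noise waveform with class-shifted fundamental and amplitude.
synth_waveform <- function(config, is_mdd, subj_effect) {
  n <- round(config$wav_rate * config$wav_duration)
  f0 <- if (is_mdd) 150 else 210          # depressed speech: lower pitch
  f0 <- f0 * (1 + 0.05 * subj_effect)
  amp <- if (is_mdd) 0.4 else 0.7         # and reduced energy
  t <- seq_len(n) / config$wav_rate
  x <- amp * sin(2 * pi * f0 * t) + stats::rnorm(n, sd = 0.05)
  audio_recording(x, config$wav_rate)
}

#' @export
print.mdd_fixture <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic paired EEG/audio fixture: %d samples (%d MDD, %d HC), %d channels\n",
              m$n_samples, m$n_mdd_samples, m$n_hc_samples,
              nrow(x$montage)))
  invisible(x)
}

fmt_matrix_csv <- function(M, path) {
  # full 17-significant-digit decimal output so the round trip is bitwise exact
  txt <- apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(colnames(M), collapse = ","), txt), path)
}

read_matrix_csv <- function(path) {
  lines <- readLines(path)
  cn <- strsplit(lines[1], ",")[[1]]
  M <- do.call(rbind, lapply(lines[-1], function(l) as.numeric(strsplit(l, ",")[[1]])))
  if (length(cn) == ncol(M) && any(nzchar(cn))) colnames(M) <- cn
  M
}

#' Write / read a fixture directory
#'
#' Lays the dataset out as one directory per subject with one CSV pair per
#' segment, plus `montage.csv`, `pairs.csv` and a top-level `manifest.json`
#' recording the configuration, seed, signal-bearing channels and the audio
#' feature-family layout. Matrices are written with 17 significant digits so
#' the round trip is bitwise lossless.
#'
#' @param fixture an [generate_dataset()] result (`audio_format = "features"`).
#' @param dir target directory.
#' @return `read_fixture()` returns the reconstructed `mdd_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  stop_if(fixture$manifest$config$audio_format != "features",
          "only feature-matrix fixtures are written to disk")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_montage(fixture$montage, file.path(dir, "montage.csv"))
  utils::write.csv(fixture$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  index <- data.frame(subject_id = vapply(fixture$samples, `[[`, "", "subject_id"),
                      segment_id = vapply(fixture$samples, `[[`, 0, "segment_id"),
                      label = vapply(fixture$samples, `[[`, "", "label"),
                      stringsAsFactors = FALSE)
  for (i in seq_along(fixture$samples)) {
    s <- fixture$samples[[i]]
    sd_dir <- file.path(dir, s$subject_id)
    dir.create(sd_dir, showWarnings = FALSE)
    fmt_matrix_csv(s$eeg, file.path(sd_dir, sprintf("eeg_%03d.csv", s$segment_id)))
    fmt_matrix_csv(s$audio, file.path(sd_dir, sprintf("audio_%03d.csv", s$segment_id)))
  }
  man <- fixture$manifest
  man$index <- index
  man$config$acoustic <- unclass(man$config$acoustic)
  man$config <- unclass(man$config)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  stop_if(!file.exists(man_path), "manifest.json missing: corrupted fixture",
          "mdgraph_integrity_error")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  stop_if(is.null(man$index) || is.null(man$config),
          "manifest.json incomplete: corrupted fixture", "mdgraph_integrity_error")
  stop_if(nrow(man$index) != man$n_samples,
          "manifest sample count does not match index", "mdgraph_integrity_error")
  montage <- read_montage(file.path(dir, "montage.csv"))
  pairs <- utils::read.csv(file.path(dir, "pairs.csv"), stringsAsFactors = FALSE)
  cfg <- man$config
  acoustic <- do.call(acoustic_config, cfg$acoustic[names(formals(acoustic_config))])
  config <- fixture_config(cfg$n_mdd_subjects, cfg$n_hc_subjects,
                           cfg$segments_per_subject, cfg$n_eeg_channels,
                           cfg$n_audio_slices, cfg$m_e, cfg$effect_size,
                           cfg$noise_sd, cfg$subject_sd, cfg$asym_frac,
                           cfg$audio_format, acoustic, cfg$wav_rate,
                           cfg$wav_duration, cfg$seed)
  samples <- vector("list", nrow(man$index))
  for (i in seq_len(nrow(man$index))) {
    sid <- man$index$subject_id[i]; seg <- man$index$segment_id[i]
    eeg <- read_matrix_csv(file.path(dir, sid, sprintf("eeg_%03d.csv", seg)))
    rownames(eeg) <- montage$label
    audio <- read_matrix_csv(file.path(dir, sid, sprintf("audio_%03d.csv", seg)))
    samples[[i]] <- list(subject_id = sid, segment_id = seg,
                         label = man$index$label[i], eeg = eeg, audio = audio)
  }
  manifest <- man[setdiff(names(man), "index")]
  manifest$config <- config
  structure(list(samples = samples, montage = montage, pairs = pairs,
                 A_eeg = combine_adjacency(build_local_adjacency(montage, k = 4),
                                           build_symmetric_adjacency(montage, pairs)),
                 A_audio = build_chain_adjacency(config$n_audio_slices),
                 acoustic_manifest = feature_manifest(acoustic),
                 manifest = manifest),
            class = "mdd_fixture")
}
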