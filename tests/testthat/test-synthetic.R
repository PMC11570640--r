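test_that("generated montages are mirrored and deterministic", {
  mont <- generate_montage(128)
  expect_equal(nrow(mont), 128)
  expect_equal(sum(mont$hemisphere == "left"), 64)
  expect_equal(sum(mont$hemisphere == "right"), 64)
  left <- mont[mont$hemisphere == "left", ]
  right <- mont[mont$hemisphere == "right", ]
  expect_equal(left$x, -right$x)
  expect_equal(left$y, right$y)
  expect_identical(generate_montage(128), mont)

  # odd channel count: one midline channel
  m5 <- generate_montage(5)
  expect_equal(sum(m5$hemisphere == "midline"), 1)
  expect_error(generate_montage(1), class = "mdgraph_parameter_error")
})

test_that("default layout counts match the emulated study", {
  cfg <- fixture_config()
  expect_equal(cfg$n_mdd_subjects * cfg$segments_per_subject, 638)
  expect_equal(cfg$n_hc_subjects * cfg$segments_per_subject, 841)
  expect_equal(cfg$n_eeg_channels, 128)
  expect_equal(cfg$n_audio_slices, 32)
})

test_that("small datasets have the configured structure and correlation", {
  fx <- tiny_fixture(seed = 41, mdd = 3, hc = 4, segs = 5, n_channels = 16)
  labels <- vapply(fx$samples, `[[`, "", "label")
  expect_equal(sum(labels == "MDD"), 15)
  expect_equal(sum(labels == "HC"), 20)
  s <- fx$samples[[1]]
  expect_equal(dim(s$eeg), c(16, 4))
  expect_equal(nrow(s$audio), 6)
  expect_equal(ncol(s$audio), nrow(fx$acoustic_manifest))
  expect_true(all(fx$manifest$signal_channels %in% fx$montage$label))

  # subject random effect: segments of one subject correlate on signal channels
  sig <- match(fx$manifest$signal_channels, rownames(s$eeg))
  subj <- vapply(fx$samples, `[[`, "", "subject_id")
  ch_mean <- vapply(fx$samples, function(s) mean(s$eeg[sig, ]), 0)
  between <- var(tapply(ch_mean, subj, mean))
  within <- mean(tapply(ch_mean, subj, var))
  expect_gt(between / (between + within), 0)   # positive intraclass correlation

  # determinism: identical config, identical dataset
  fx2 <- tiny_fixture(seed = 41, mdd = 3, hc = 4, segs = 5, n_channels = 16)
  expect_identical(fx$samples, fx2$samples)
})

test_that("class signal lands where the manifest says", {
  fx <- tiny_fixture(seed = 43, mdd = 6, hc = 6, segs = 8, n_channels = 16,
                     effect_size = 1)
  labels <- vapply(fx$samples, `[[`, "", "label")
  sig <- match(fx$manifest$signal_channels, fx$montage$label)
  eeg_mean <- function(idx, rows) {
    mean(vapply(fx$samples[idx], function(s) mean(s$eeg[rows, ]), 0))
  }
  gap_sig <- eeg_mean(labels == "MDD", sig) - eeg_mean(labels == "HC", sig)
  nonsig <- setdiff(seq_len(16), sig)
  gap_non <- eeg_mean(labels == "MDD", nonsig) - eeg_mean(labels == "HC", nonsig)
  expect_gt(gap_sig, 0.5)             # roughly the configured shift
  expect_lt(abs(gap_non), 0.4)        # no systematic shift off-signal

  # left-hemisphere signal channels shifted more than right (asymmetry)
  sl <- match(fx$manifest$signal_channels_left, fx$montage$label)
  sr <- match(fx$manifest$signal_channels_right, fx$montage$label)
  gap_l <- eeg_mean(labels == "MDD", sl) - eeg_mean(labels == "HC", sl)
  gap_r <- eeg_mean(labels == "MDD", sr) - eeg_mean(labels == "HC", sr)
  expect_gt(gap_l, gap_r)

  # audio: pitch/energy/mel-mean columns shifted for the depressed class
  cols <- fx$manifest$audio_signal_columns
  aud_mean <- function(idx, cc) {
    mean(vapply(fx$samples[idx], function(s) mean(s$audio[, cc]), 0))
  }
  expect_gt(aud_mean(labels == "MDD", cols) - aud_mean(labels == "HC", cols), 0.3)
})

test_that("a null generator leaves the classes indistinguishable", {
  fx <- tiny_fixture(seed = 47, effect_size = 0, mdd = 8, hc = 8, segs = 6,
                     n_channels = 20)
  labels <- vapply(fx$samples, `[[`, "", "label")
  subj <- vapply(fx$samples, `[[`, "", "subject_id")
  # aggregate to subject level first (segments share a subject random effect)
  ch <- vapply(fx$samples, function(s) rowMeans(s$eeg), numeric(20))
  subj_means <- vapply(unique(subj), function(s) rowMeans(ch[, subj == s, drop = FALSE]),
                       numeric(20))
  subj_lab <- labels[match(unique(subj), subj)]
  pvals <- vapply(seq_len(20), function(i) {
    t.test(subj_means[i, subj_lab == "MDD"], subj_means[i, subj_lab == "HC"])$p.value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("waveform fixtures carry a pitch and energy contrast", {
  fx <- generate_dataset(fixture_config(
    n_mdd_subjects = 2, n_hc_subjects = 2, segments_per_subject = 2,
    n_eeg_channels = 8, n_audio_slices = 4, m_e = 4,
    audio_format = "waveform", wav_rate = 8000, wav_duration = 0.5, seed = 51))
  labels <- vapply(fx$samples, `[[`, "", "label")
  recs <- lapply(fx$samples, `[[`, "audio")
  expect_true(all(vapply(recs, inherits, TRUE, "audio_recording")))
  rms <- vapply(recs, function(r) sqrt(mean(r$samples^2)), 0)
  expect_lt(mean(rms[labels == "MDD"]), mean(rms[labels == "HC"]))
  # the slice features of a depressed recording show the lower pitch
  f_mdd <- compute_slice_features(recs[[which(labels == "MDD")[1]]],
                                  acoustic_config(n_fft = 1024, hop = 512))
  f_hc <- compute_slice_features(recs[[which(labels == "HC")[1]]],
                                 acoustic_config(n_fft = 1024, hop = 512))
  expect_lt(f_mdd["pitch_mean"], f_hc["pitch_mean"])
})

test_that("fixtures round-trip through the directory layout", {
  fx <- tiny_fixture(seed = 53, mdd = 2, hc = 2, segs = 2, n_channels = 8,
                     n_slices = 4)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$seed, 53)
  expect_equal(nrow(man$index), length(fx$samples))

  back <- read_fixture(dir)
  expect_equal(length(back$samples), length(fx$samples))
  for (i in seq_along(fx$samples)) {
    expect_identical(back$samples[[i]]$eeg, fx$samples[[i]]$eeg)
    expect_identical(back$samples[[i]]$audio, fx$samples[[i]]$audio)
    expect_identical(back$samples[[i]]$label, fx$samples[[i]]$label)
  }
  expect_equal(back$A_eeg, fx$A_eeg)

  # corrupted manifest is detected
  writeLines("{}", file.path(dir, "manifest.json"))
  expect_error(read_fixture(dir), class = "mdgraph_integrity_error")
})
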