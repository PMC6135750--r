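# Generator contracts: determinism, noiseless limits, label effects.

test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_config(coupling_kappa = 1.5),
               class = "affectpipe_bad_config")
  expect_error(synthetic_config(lf_amp_ms = -1),
               class = "affectpipe_bad_config")
  expect_error(synthetic_config(window_s = 0),
               class = "affectpipe_bad_config")
  expect_error(synthetic_config(fs = 60),
               class = "affectpipe_bad_config")
})

test_that("noiseless RR limit is a constant series at the configured mean", {
  cfg <- synthetic_config(lf_amp_ms = 0, hf_amp_ms = 0, rr_jitter_ms = 0,
                          rr_mean_ms = 800, window_s = 60)
  rr <- generate_rr_series(cfg)
  expect_true(all(abs(rr$intervals_ms - 800) < 1e-9))
  # 60 000 ms / 800 ms beats, one-beat tolerance for the boundary
  expect_lte(abs(length(rr$intervals_ms) - 75), 1)
  expect_error(generate_rr_series(synthetic_config(rr_mean_ms = 1400)),
               class = "affectpipe_bad_config")
})

test_that("arousal effect shifts the generated LF/HF balance", {
  # parameter-recovery oracle: the spectral estimator applied to series
  # generated under the two labels, over seeded replicates
  ratios <- sapply(1:20, function(s) {
    set.seed(s)
    cfg <- synthetic_config(arousal_effect = 2, window_s = 120,
                            rr_jitter_ms = 5)
    hi <- frequency_domain(detrend_rr(generate_rr_series(cfg, TRUE)))
    lo <- frequency_domain(detrend_rr(generate_rr_series(cfg, FALSE)))
    hi$lf_hf / lo$lf_hf
  })
  expect_gt(mean(ratios), 1.5)
})

test_that("ECG template placement matches ground truth beat times", {
  cfg <- synthetic_config(rr_jitter_ms = 0, window_s = 60)
  rr <- generate_rr_series(cfg)
  ecg <- generate_ecg(rr, fs = 256)
  truth <- attr(ecg, "truth_beats")
  pk <- attr(detect_r_peaks(ecg), "peak_indices")
  expect_equal(length(pk), length(truth))
  expect_true(all(abs(pk - truth) <= 1))
})

test_that("noisy ECG at ~10 dB SNR still yields near-perfect detection", {
  set.seed(11)
  cfg <- synthetic_config(rr_jitter_ms = 10, window_s = 60)
  rr <- generate_rr_series(cfg)
  clean <- generate_ecg(rr, fs = 256)
  noise_sd <- sqrt(mean(clean$samples^2) / 10)   # 10 dB SNR
  ecg <- generate_ecg(rr, fs = 256, noise_sd = noise_sd, wander_uv = 60)
  truth <- attr(ecg, "truth_beats")
  pk <- attr(detect_r_peaks(ecg), "peak_indices")
  tol <- round(0.020 * 256)
  hits <- sum(vapply(truth, function(b) any(abs(pk - b) <= tol), logical(1)))
  expect_gte(hits / length(truth), 0.99)
})

test_that("empty RR series produces an empty waveform", {
  ecg <- generate_ecg(rr_series(numeric(0)), fs = 256)
  expect_length(ecg$samples, 0)
})

test_that("EEG generator enforces the 9-channel montage", {
  expect_error(eeg_record(matrix(0, 100, 8), 256),
               class = "affectpipe_bad_input")
})

test_that("beta band power scales with the square of the arousal effect", {
  pows <- sapply(1:5, function(s) {
    set.seed(s)
    cfg2 <- synthetic_config(arousal_effect = 2, eeg_noise_sd = 0)
    cfg1 <- synthetic_config(arousal_effect = 1, eeg_noise_sd = 0)
    hi <- generate_eeg(cfg2, arousal_high = TRUE)
    lo <- generate_eeg(cfg1, arousal_high = TRUE)
    bp_hi <- band_power(epoch_and_reject(hi))
    bp_lo <- band_power(epoch_and_reject(lo))
    mean(bp_hi[, "beta"]) / mean(bp_lo[, "beta"])
  })
  expect_rel(mean(pows), 4, 0.2)
})

test_that("artifact injection at rate 0 is the identity", {
  set.seed(5)
  eeg <- generate_eeg(synthetic_config())
  out <- inject_artifacts(eeg, 0)
  expect_identical(out$signals, eeg$signals)
  expect_length(attr(out, "corrupted_epochs"), 0)
})

test_that("epoch rejection recovers injected artifact ground truth", {
  set.seed(6)
  eeg <- generate_eeg(synthetic_config())
  bad <- inject_artifacts(eeg, 0.2)
  truth <- attr(bad, "corrupted_epochs")
  ep <- epoch_and_reject(filter_and_baseline(bad))
  flagged <- which(ep$rejected)
  expect_gte(mean(truth %in% flagged), 0.90)
  clean <- setdiff(seq_along(ep$rejected), truth)
  expect_lte(mean(clean %in% flagged), 0.05)
})

test_that("a channel flat for 15% of the window is the one flagged", {
  set.seed(7)
  eeg <- flatten_channel(generate_eeg(synthetic_config()), "C3", 0.15)
  qc <- detect_corrupted_channels(eeg)
  expect_identical(qc$channel[qc$corrupted], "C3")
})

test_that("dataset generation is balanced, complete and deterministic", {
  cfg <- synthetic_config(n_subjects = 8, seed = 42)
  ds <- generate_dataset(cfg)
  expect_length(ds$records, 32)
  expect_equal(mean(ds$manifest$arousal_label), 0.5)
  expect_equal(mean(ds$manifest$valence_label), 0.5)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$records[[5]]$eeg$signals, ds2$records[[5]]$eeg$signals)
  expect_error(generate_dataset(synthetic_config(n_subjects = 4)),
               class = "affectpipe_bad_config")
})
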