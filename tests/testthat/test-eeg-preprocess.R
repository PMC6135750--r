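# Channel QC, interpolation, filtering, epoch rejection, ICA hook.

gauss_eeg <- function(n = 256 * 30, fs = 256, sd = 10, seed = 1) {
  set.seed(seed)
  eeg_record(matrix(rnorm(n * 9, 0, sd), n, 9), fs)
}

test_that("channel QC: clean channels pass, impulse-train channel fails", {
  eeg <- gauss_eeg()
  qc <- detect_corrupted_channels(eeg)
  expect_false(any(qc$corrupted))
  expect_identical(unique(qc$action), "none")

  spiky <- eeg
  idx <- seq(100, nrow(spiky$signals), by = 500)
  spiky$signals[idx, 4] <- 300
  qc2 <- detect_corrupted_channels(spiky)
  expect_identical(qc2$channel[qc2$corrupted], "Cz")
})

test_that("interpolation reproduces a constant neighborhood and is local", {
  set.seed(2)
  s <- sin(2 * pi * 10 * (1:(256 * 12)) / 256)
  sig <- matrix(rep(s, 9), ncol = 9)
  sig[, 5] <- rnorm(length(s), 0, 50)
  eeg <- eeg_record(sig, 256)
  out <- interpolate_channel(eeg, "C3")
  expect_equal(out$signals[, 5], s, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(out$signals[, -5], eeg$signals[, -5])
})

test_that("two corrupted channels reject the subject", {
  eeg <- gauss_eeg(seed = 3)
  eeg <- flatten_channel(eeg, "F3", 0.2)
  eeg <- flatten_channel(eeg, "P4", 0.2)
  qc <- detect_corrupted_channels(eeg)
  expect_identical(unique(qc$action), "subject_rejected")
  expect_error(interpolate_channel(eeg, qc),
               class = "affectpipe_subject_rejected")
})

test_that("filtering removes DC and 60 Hz but keeps the 10 Hz passband", {
  fs <- 256
  t <- (1:(fs * 20)) / fs
  mk <- function(x) eeg_record(matrix(rep(x, 9), ncol = 9), fs)
  out_dc <- filter_and_baseline(mk(50 + sin(2 * pi * 10 * t)))
  expect_lt(abs(mean(out_dc$signals[, 1])), 0.5)

  amp_at <- function(x, f) {
    flt <- filter_and_baseline(mk(x))$signals[, 1]
    n <- length(flt)
    2 * Mod(fft(flt))[round(f * n / fs) + 1] / n
  }
  expect_lt(amp_at(sin(2 * pi * 60 * t), 60), 10^(-20 / 20))  # >= 20 dB down
  expect_gt(amp_at(sin(2 * pi * 10 * t), 10), 0.95)           # within 5%
})

test_that("epoch rejection follows the >2-channel amplitude rule", {
  set.seed(4)
  fs <- 256
  t <- (1:(fs * 40)) / fs
  sig <- sapply(1:9, function(ch)
    20 * sin(2 * pi * 10 * t + ch) + rnorm(length(t), 0, 3))
  ep0 <- epoch_and_reject(eeg_record(sig, fs))
  expect_equal(sum(ep0$rejected), 0)

  blink <- exp(-((1:fs) - 128)^2 / 30^2) * 150
  sig3 <- sig
  sig3[(5 * fs + 1):(6 * fs), 1:3] <- sig3[(5 * fs + 1):(6 * fs), 1:3] + blink
  ep3 <- epoch_and_reject(eeg_record(sig3, fs))
  expect_true(ep3$rejected[6])
  expect_match(ep3$reasons[6], "amplitude")

  sig2 <- sig
  sig2[(5 * fs + 1):(6 * fs), 1:2] <- sig2[(5 * fs + 1):(6 * fs), 1:2] + blink
  ep2 <- epoch_and_reject(eeg_record(sig2, fs))
  amp_flagged <- grepl("amplitude", ep2$reasons[6])
  expect_false(amp_flagged)
})

test_that("epoch partition is exact and rejection is idempotent", {
  set.seed(6)
  eeg <- inject_artifacts(generate_eeg(synthetic_config()), 0.1)
  ep <- epoch_and_reject(filter_and_baseline(eeg))
  expect_length(ep$rejected, 90)
  expect_equal(sum(ep$rejected) + sum(!ep$rejected), 90)
  expect_true(all(ep$reasons[ep$rejected] != ""))
  expect_true(all(ep$reasons %in% c("", "kurtosis", "amplitude",
                                    "kurtosis,amplitude")))
  # rebuild a record from retained epochs only; nothing new is rejected
  keep <- which(!ep$rejected)
  flat <- do.call(rbind, lapply(keep, function(e) t(ep$epochs[e, , ])))
  ep2 <- epoch_and_reject(eeg_record(flat, ep$fs))
  expect_lte(sum(ep2$rejected), 0.05 * length(keep))
})

test_that("clean synthetic input retains at least 95% of epochs", {
  retained <- sapply(1:20, function(s) {
    set.seed(s)
    eeg <- generate_eeg(synthetic_config(artifact_rate = 0))
    ep <- epoch_and_reject(filter_and_baseline(eeg))
    mean(!ep$rejected)
  })
  expect_gte(mean(retained), 0.95)
})

test_that("ICA with no flagged components reconstructs the input", {
  set.seed(7)
  eeg <- generate_eeg(synthetic_config())
  ep <- epoch_and_reject(filter_and_baseline(eeg))
  out <- remove_ica_artifacts(ep, policy = "manual", mask = rep(FALSE, 9))
  expect_equal(out$epochs, ep$epochs, tolerance = 1e-8)
})

test_that("ICA auto policy removes a planted frontal blink source", {
  set.seed(8)
  fs <- 256
  eeg <- generate_eeg(synthetic_config(eeg_noise_sd = 2))
  n <- nrow(eeg$signals)
  # slow high-kurtosis blink train mixed into the three frontal channels
  blink <- numeric(n)
  at <- seq(fs, n - 2 * fs, by = round(2.5 * fs))
  for (a in at) blink[a:(a + fs - 1)] <- exp(-((1:fs) - 128)^2 / 35^2) * 90
  mix <- c(Fz = 1, F3 = 0.8, F4 = 0.85)
  for (ch in names(mix)) {
    eeg$signals[, ch] <- eeg$signals[, ch] + mix[[ch]] * blink
  }
  ep <- epoch_and_reject(filter_and_baseline(eeg), amp_thr = 1e9,
                         grad_thr = 1e9, kurt_z = 1e9)  # keep all epochs
  out <- remove_ica_artifacts(ep, policy = "auto")
  expect_gt(length(attr(out, "ica_flagged")), 0)
  lowfreq_frontal <- function(e) {
    tot <- 0
    for (ch in 1:3) {
      x <- as.vector(t(e$epochs[, ch, ]))   # samples in temporal order
      w <- welch_psd(x, fs, nperseg = 2 * fs)
      tot <- tot + band_power_psd(w$freq, w$psd, 0.5, 4)
    }
    tot
  }
  expect_lt(lowfreq_frontal(out), 0.3 * lowfreq_frontal(ep))
})

test_that("subjects with more than a third of epochs affected are rejected", {
  set.seed(9)
  eeg <- generate_eeg(synthetic_config())
  ep <- epoch_and_reject(filter_and_baseline(eeg))
  ep$rejected[1:36] <- TRUE                     # 40% artifact-affected
  expect_error(remove_ica_artifacts(ep),
               class = "affectpipe_subject_rejected")
})
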