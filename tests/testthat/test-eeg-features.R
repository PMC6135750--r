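# Band power, mean phase coherence and feature-vector assembly.

epochs_from <- function(sig, fs = 256) epoch_and_reject(eeg_record(sig, fs))

test_that("a 10 Hz tone lands almost entirely in the alpha band", {
  fs <- 256
  t <- (1:(fs * 30)) / fs
  set.seed(1)
  sig <- matrix(rnorm(length(t) * 9, 0, 0.01), ncol = 9)
  sig[, 3] <- sig[, 3] + sin(2 * pi * 10 * t)
  bp <- band_power(epochs_from(sig))
  expect_identical(dim(bp), c(9L, 4L))
  expect_true(all(bp >= 0))
  expect_gte(bp[3, "alpha"] / sum(bp[3, ]), 0.95)
  # a unit-amplitude sinusoid carries power 1/2
  expect_rel(bp[3, "alpha"], 0.5, 0.05)
})

test_that("white-noise power splits across bands by bandwidth", {
  fs <- 256
  set.seed(2)
  sig <- matrix(rnorm(fs * 60 * 9), ncol = 9)
  bp <- band_power(epochs_from(sig))
  widths <- vapply(EEG_BANDS, diff, numeric(1))
  obs <- colMeans(bp)
  ratio <- (obs / widths) / (sum(obs) / sum(widths))
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("band power scales quadratically with amplitude", {
  fs <- 256
  set.seed(3)
  cfg <- synthetic_config(eeg_noise_sd = 0)
  eeg <- generate_eeg(cfg)
  # absolute rejection thresholds are deliberately disabled: the check
  # isolates the estimator, and doubling would otherwise cross the
  # 100 uV rule on different epochs
  ep1 <- epoch_and_reject(eeg_record(eeg$signals, fs), amp_thr = Inf,
                          grad_thr = Inf)
  ep2 <- epoch_and_reject(eeg_record(2 * eeg$signals, fs), amp_thr = Inf,
                          grad_thr = Inf)
  bp1 <- band_power(ep1)
  bp2 <- band_power(ep2)
  expect_true(all(abs(bp2 / bp1 - 4) < 0.04))
})

test_that("MPC is 1 for identical and constant-lag channels", {
  fs <- 256
  t <- (1:(fs * 30)) / fs
  base <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 6 * t)
  sig <- sapply(1:9, function(ch) base)
  mpc <- mean_phase_coherence(epochs_from(sig))
  for (b in names(mpc)) {
    expect_true(all(abs(mpc[[b]] - 1) < 1e-6))
  }
  # fixed phase lag per channel: dispersion of the phase difference is 0
  lagged <- sapply(1:9, function(ch) sin(2 * pi * 10 * t + (ch - 1) * 0.4))
  mpc_l <- mean_phase_coherence(epochs_from(lagged))
  expect_true(all(abs(mpc_l$alpha - 1) < 1e-3))
})

test_that("independent channels give low MPC in every band", {
  means <- sapply(1:5, function(s) {
    set.seed(s)
    eeg <- generate_eeg(synthetic_config(coupling_kappa = 0,
                                         eeg_noise_sd = 0))
    mpc <- mean_phase_coherence(epochs_from(eeg$signals))
    vapply(mpc, function(R) mean(R[upper.tri(R)]), numeric(1))
  })
  expect_true(all(rowMeans(means) < 0.3))
})

test_that("MPC matrices are symmetric, unit-diagonal and within [0,1]", {
  set.seed(6)
  eeg <- generate_eeg(synthetic_config(coupling_kappa = 0.5))
  mpc <- mean_phase_coherence(epochs_from(eeg$signals))
  expect_length(mpc, 4)
  for (R in mpc) {
    expect_identical(R, t(R))
    expect_true(all(diag(R) == 1))
    expect_true(all(R >= 0 & R <= 1))
    expect_length(R[upper.tri(R)], 36)
  }
})

test_that("MPC rises monotonically with the planted coupling", {
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  reps <- sapply(1:3, function(s) {
    sapply(kappas, function(k) {
      set.seed(s)
      eeg <- generate_eeg(synthetic_config(coupling_kappa = k,
                                           eeg_noise_sd = 0))
      mpc <- mean_phase_coherence(epochs_from(eeg$signals))
      mean(vapply(mpc, function(R) mean(R[upper.tri(R)]), numeric(1)))
    })
  })
  rho <- cor(kappas, rowMeans(reps), method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("assembled feature vector has the 26+36+144 block structure", {
  set.seed(7)
  cfg <- synthetic_config()
  ecg <- generate_ecg(generate_rr_series(cfg), cfg$fs, noise_sd = 10,
                      duration_s = 90)
  hrv <- hrv_feature_vector(ecg)
  eeg <- generate_eeg(cfg)
  ep <- epochs_from(eeg$signals)
  fv <- assemble_feature_vector(hrv, band_power(ep),
                                mean_phase_coherence(ep))
  blocks <- attr(fv, "blocks")
  expect_length(blocks$hrv, 26)
  expect_length(blocks$band_power, 36)
  expect_length(blocks$mpc, 144)
  expect_length(fv, 206)
  expect_false(any(duplicated(names(fv))))
  fv2 <- assemble_feature_vector(hrv, band_power(ep),
                                 mean_phase_coherence(ep))
  expect_identical(names(fv), names(fv2))
  expect_error(assemble_feature_vector(hrv, NULL,
                                       mean_phase_coherence(ep)),
               class = "affectpipe_bad_input")
})

test_that("feature tables round-trip through text bit-exactly", {
  set.seed(8)
  df <- data.frame(subject = "S01", stimulus = 1L,
                   t(runif(10, -1e3, 1e3)))
  path <- tempfile(fileext = ".csv")
  write_feature_table(df, path)
  back <- read_feature_table(path)
  for (j in 3:12) expect_identical(back[[j]], df[[j]])
})
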