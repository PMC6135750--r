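# Per-stimulus EEG features: Welch band power (9 channels x 4 bands) and
# mean phase coherence (36 channel pairs x 4 bands), both averaged over
# the retained 1 s epochs of the stimulus window.

#' Welch band power per channel and band
#'
#' Each retained 1 s epoch contributes a Hann-tapered periodogram (one
#' full-epoch segment by default, giving 1 Hz resolution -- just enough
#' to separate the 4-Hz-wide theta and alpha bands); the per-band power
#' is integrated over the band limits and the per-stimulus value is the
#' mean over retained epochs, which makes the whole estimate a Welch
#' average with 1 s segments over the stimulus window. Sub-epoch
#' segmentation (e.g. `nperseg = fs/2` for 0.5 s segments with 50%
#' overlap) remains available at the cost of frequency resolution.
#'
#' @param ep an `epoched_eeg` with at least one retained epoch.
#' @param bands band edges, default [EEG_BANDS].
#' @param nperseg Welch segment length in samples within each epoch
#'   (default: the full epoch).
#' @return object of class `band_power_block`: 9 x 4 matrix (uV^2),
#'   rownames = channels, colnames = bands.
#' @export
band_power <- function(ep, bands = EEG_BANDS, nperseg = NULL) {
  keep <- which(!ep$rejected)
  if (length(keep) == 0) {
    reject("no retained epochs; band power undefined",
           "affectpipe_unusable_window")
  }
  fs <- ep$fs
  nper <- as.integer(nperseg %||% fs)
  nper <- min(nper, fs)
  step <- nper %/% 2L
  starts <- seq(1L, fs - nper + 1L, by = step)
  win <- hann_window(nper)
  scale <- fs * sum(win^2)
  nf <- nper %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nper
  dbl <- rep(2, nf); dbl[1] <- 1; if (nper %% 2L == 0L) dbl[nf] <- 1
  E <- length(keep)
  out <- matrix(0, 9L, length(bands),
                dimnames = list(ep$labels, names(bands)))
  for (ch in 1:9) {
    M <- ep$epochs[keep, ch, , drop = TRUE]
    if (E == 1) M <- matrix(M, 1L)
    if (length(starts) == 1L) {        # one full-epoch segment per epoch
      segs <- t(M - rowMeans(M)) * win
    } else {
      # columns: every Welch segment of every retained epoch
      segs <- matrix(0, nper, length(starts) * E)
      col <- 1L
      for (e in seq_len(E)) {
        for (s0 in starts) {
          seg <- M[e, s0:(s0 + nper - 1L)]
          segs[, col] <- (seg - mean(seg)) * win
          col <- col + 1L
        }
      }
    }
    spec <- Mod(stats::mvfft(segs))^2 / scale
    spec <- spec[seq_len(nf), , drop = FALSE] * dbl
    # mean over segments/epochs commutes with the band integral
    psd_mean <- rowMeans(spec)
    for (b in seq_along(bands)) {
      e_ <- bands[[b]]
      out[ch, b] <- band_power_psd(freq, psd_mean, e_[1], e_[2])
    }
  }
  structure(out, class = c("band_power_block", "matrix", "array"))
}

#' Mean phase coherence between all channel pairs, per band
#'
#' For each band and 1 s epoch, every channel is reduced to its
#' band-limited analytic signal (frequency-domain band selection with a
#' raised-cosine edge taper, positive frequencies only -- the combined
#' band-pass + Hilbert step) and the first and last 10% of phase samples
#' are discarded to suppress edge effects. For every channel pair the
#' coherence is `R = |E[exp(i * dphi)]|`, equivalently
#' `R^2 = E[cos dphi]^2 + E[sin dphi]^2`, with the expectation taken
#' over all retained phase samples of the stimulus (per-epoch complex
#' mean phasors averaged across epochs, modulus last -- taking the
#' modulus per epoch first would inflate the independence baseline in
#' the slow bands, where one second spans too few phase decorrelation
#' times).
#'
#' @param ep an `epoched_eeg` with at least one retained epoch.
#' @param bands band edges, default [EEG_BANDS].
#' @param edge_trim fraction of phase samples discarded at each epoch
#'   edge (default 0.1).
#' @return object of class `mpc_block`: list of 9 x 9 symmetric matrices
#'   (one per band, unit diagonal, entries in [0, 1]).
#' @export
mean_phase_coherence <- function(ep, bands = EEG_BANDS, edge_trim = 0.1) {
  keep <- which(!ep$rejected)
  if (length(keep) == 0) {
    reject("no retained epochs; MPC undefined", "affectpipe_unusable_window")
  }
  fs <- ep$fs
  n <- dim(ep$epochs)[3]
  E <- length(keep)
  trim <- round(edge_trim * n)
  use <- (trim + 1L):(n - trim)
  # samples x (channel, epoch) matrix for one mvfft per band
  X <- matrix(0, n, 9L * E)
  for (i in seq_len(E)) {
    X[, ((i - 1L) * 9L + 1L):(i * 9L)] <- t(ep$epochs[keep[i], , ])
  }
  Xf <- stats::mvfft(X)
  freq <- (seq_len(n) - 1L) * fs / n
  out <- list()
  for (b in names(bands)) {
    e_ <- bands[[b]]
    gain <- band_analytic_gain(freq, e_[1], e_[2])
    Z <- stats::mvfft(Xf * gain, inverse = TRUE) / n
    Z <- Z[use, , drop = FALSE]
    Z <- Z / Mod(Z)                       # unit phasors exp(i*phi)
    Z[!is.finite(Z)] <- 0
    zch <- lapply(1:9, function(a)
      Z[, (seq_len(E) - 1L) * 9L + a, drop = FALSE])
    R <- matrix(0, 9L, 9L, dimnames = list(ep$labels, ep$labels))
    for (a in 1:8) for (cc in (a + 1L):9L) {
      # per-epoch complex mean phasor, pooled across epochs before the
      # modulus: Eq.-1's expectation taken over the whole stimulus
      r_ep <- colMeans(zch[[a]] * Conj(zch[[cc]]))
      R[a, cc] <- R[cc, a] <- min(1, Mod(mean(r_ep)))
    }
    diag(R) <- 1
    out[[b]] <- R
  }
  structure(out, class = "mpc_block")
}

# Positive-frequency band selector with raised-cosine edges (10% of band
# width), doubling positive frequencies: its inverse FFT is the
# band-limited analytic signal.
band_analytic_gain <- function(freq, lo, hi) {
  n <- length(freq)
  nyq_i <- if (n %% 2L == 0L) n %/% 2L + 1L else (n + 1L) %/% 2L
  g <- numeric(n)
  roll <- 0.1 * (hi - lo)
  pos <- 2:nyq_i
  f <- freq[pos]
  amp <- numeric(length(f))
  amp[f >= lo + roll & f <= hi - roll] <- 1
  up <- f >= lo - roll & f < lo + roll
  amp[up] <- 0.5 * (1 + sin(pi * (f[up] - lo) / (2 * roll)))
  dn <- f > hi - roll & f <= hi + roll
  amp[dn] <- 0.5 * (1 - sin(pi * (f[dn] - hi) / (2 * roll)))
  g[pos] <- 2 * amp
  if (n %% 2L == 0L) g[nyq_i] <- g[nyq_i] / 2
  g
}

#' Assemble the per-stimulus feature vector
#'
#' Concatenates the HRV block (26 features), the band-power block (36)
#' and the MPC block (144 = 36 pairs x 4 bands) into one named vector
#' with stable ordering; the block boundaries are recorded for the
#' block-wise PCA stage.
#'
#' @param hrv named HRV vector from [hrv_feature_vector()].
#' @param bp `band_power_block` from [band_power()].
#' @param mpc `mpc_block` from [mean_phase_coherence()].
#' @return named numeric vector of length 206 with attribute `blocks`
#'   (named list of index ranges).
#' @export
assemble_feature_vector <- function(hrv, bp, mpc) {
  if (missing(hrv) || missing(bp) || missing(mpc) ||
      is.null(hrv) || is.null(bp) || is.null(mpc)) {
    reject("all three feature blocks are required", "affectpipe_bad_input")
  }
  hv <- as.numeric(hrv)
  names(hv) <- paste0("hrv_", HRV_FEATURE_NAMES)
  bv <- as.numeric(bp)
  names(bv) <- paste0("bp_", outer(rownames(bp), colnames(bp), paste,
                                   sep = "_"))
  mv <- numeric(0)
  for (b in names(mpc)) {
    R <- mpc[[b]]
    ut <- which(upper.tri(R), arr.ind = TRUE)
    v <- R[upper.tri(R)]
    names(v) <- paste("mpc", b, rownames(R)[ut[, 1]],
                      colnames(R)[ut[, 2]], sep = "_")
    mv <- c(mv, v)
  }
  out <- c(hv, bv, mv)
  attr(out, "blocks") <- list(
    hrv = seq_along(hv),
    band_power = length(hv) + seq_along(bv),
    mpc = length(hv) + length(bv) + seq_along(mv)
  )
  out
}
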