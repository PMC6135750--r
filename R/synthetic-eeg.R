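# Oscillator-sum EEG generator. Each channel is one narrow-band oscillator
# per band (theta/alpha/beta/gamma) plus a pink-noise floor. Inter-channel
# phase coupling is planted by mixing a band-wide shared oscillator into
# every channel with weight kappa; channel-private oscillators get a random
# frequency inside the band plus Wiener phase drift so that uncoupled
# channels are genuinely asynchronous. Band power and coupling weight have
# closed-form ground truth, which is what the estimator tests lean on.

#' Construct an EEG record object
#'
#' @param signals numeric matrix, samples x 9 channels (uV).
#' @param fs sampling rate, Hz.
#' @param labels channel labels; defaults to the canonical 9-channel
#'   10-20 montage [EEG_CHANNELS].
#' @export
eeg_record <- function(signals, fs, labels = EEG_CHANNELS) {
  signals <- as.matrix(signals)
  if (ncol(signals) != 9L) {
    reject("EEG records must have exactly 9 channels",
           "affectpipe_bad_input")
  }
  colnames(signals) <- labels
  structure(list(signals = signals, fs = fs,
                 labels = labels,
                 duration_s = nrow(signals) / fs),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> 9 ch x %.1f s at %g Hz\n", x$duration_s, x$fs))
  invisible(x)
}

#' Generate a synthetic 9-channel EEG window
#'
#' Per channel and band the signal is
#' `amp_b * (sqrt(1-k) cos(phi_private(t)) + sqrt(k) cos(phi_shared(t)))`
#' where the private oscillator has a channel-specific frequency drawn
#' from the inner half of the band plus Wiener phase drift, and the shared
#' oscillator sits at the band center with a common phase. Because the two
#' components are uncorrelated, every channel's expected band power is
#' `amp_b^2 / 2` independent of the coupling weight `k`. For high-arousal
#' windows the beta amplitude is multiplied by `arousal_effect`; for
#' positive-valence windows `k = min(1, coupling_kappa * valence_effect)`.
#'
#' @param cfg a [synthetic_config()].
#' @param arousal_high,valence_positive logical window labels.
#' @param phase_drift_sd per-sample sd (radians) of the private
#'   oscillators' phase random walk; 0 gives pure sinusoids.
#' @return `eeg_record` with attribute `truth`: effective band amplitudes,
#'   expected band powers (uV^2), coupling weight, and oscillator
#'   frequencies.
#' @export
generate_eeg <- function(cfg, arousal_high = FALSE, valence_positive = FALSE,
                         phase_drift_sd = 0.15) {
  if (cfg$window_s < 10) {
    reject("window_s must be >= 10 s", "affectpipe_bad_config")
  }
  fs <- cfg$fs
  n <- round(cfg$window_s * fs)
  t <- (seq_len(n) - 1L) / fs
  amps <- cfg$band_amps
  if (isTRUE(arousal_high)) amps[["beta"]] <- amps[["beta"]] * cfg$arousal_effect
  kappa <- cfg$coupling_kappa
  if (isTRUE(valence_positive)) kappa <- min(1, kappa * cfg$valence_effect)
  sig <- matrix(0, n, 9L)
  freqs <- list()
  for (b in names(EEG_BANDS)) {
    band <- EEG_BANDS[[b]]
    width <- band[2] - band[1]
    f_shared <- mean(band)
    phi_shared <- stats::runif(1, 0, 2 * pi)
    shared <- cos(2 * pi * f_shared * t + phi_shared)
    f_priv <- stats::runif(9L, band[1] + 0.25 * width, band[2] - 0.25 * width)
    freqs[[b]] <- list(shared = f_shared, private = f_priv)
    for (ch in 1:9) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      drift <- if (phase_drift_sd > 0) {
        cumsum(stats::rnorm(n, 0, phase_drift_sd))
      } else 0
      priv <- cos(2 * pi * f_priv[ch] * t + phi0 + drift)
      sig[, ch] <- sig[, ch] +
        amps[[b]] * (sqrt(1 - kappa) * priv + sqrt(kappa) * shared)
    }
  }
  if (cfg$eeg_noise_sd > 0) {
    for (ch in 1:9) {
      sig[, ch] <- sig[, ch] + cfg$eeg_noise_sd * pink_noise(n)
    }
  }
  out <- eeg_record(sig, fs)
  attr(out, "truth") <- list(
    band_amps = amps,
    band_power = vapply(amps, function(a) a^2 / 2, numeric(1)),
    kappa = kappa,
    freqs = freqs
  )
  out
}

#' Corrupt randomly chosen 1 s spans of an EEG record
#'
#' Each corrupted span receives either a blink-like transient (a 300 ms
#' smooth deflection exceeding 100 uV on the four anterior channels) or a
#' step artifact (an abrupt >70 uV/sample jump on three channels). The
#' corrupted epoch indices are returned as ground truth so the downstream
#' rejection rules can be scored. Channel flattening (the third artifact
#' family) acts at the whole-channel level and is provided separately by
#' [flatten_channel()].
#'
#' @param eeg an `eeg_record`.
#' @param artifact_rate fraction of 1 s epochs to corrupt.
#' @param types artifact families to sample from.
#' @return `eeg_record` with attributes `corrupted_epochs` (1-based epoch
#'   indices) and `artifact_types`.
#' @export
inject_artifacts <- function(eeg, artifact_rate,
                             types = c("blink", "step")) {
  if (artifact_rate < 0 || artifact_rate > 1) {
    reject("artifact_rate must lie in [0, 1]", "affectpipe_bad_config")
  }
  fs <- round(eeg$fs)
  n_ep <- floor(nrow(eeg$signals) / fs)
  n_bad <- round(artifact_rate * n_ep)
  out <- eeg
  if (n_bad == 0) {
    attr(out, "corrupted_epochs") <- integer(0)
    attr(out, "artifact_types") <- character(0)
    return(out)
  }
  bad <- sort(sample.int(n_ep, n_bad))
  kind <- sample(types, n_bad, replace = TRUE)
  sig <- out$signals
  for (i in seq_along(bad)) {
    s0 <- (bad[i] - 1L) * fs
    if (kind[i] == "blink") {
      len <- round(0.3 * fs)
      at <- s0 + sample.int(fs - len, 1L)
      pulse <- 150 * exp(-((seq_len(len) - len / 2)^2) / (len / 6)^2)
      for (ch in c("Fz", "F3", "F4", "Cz")) {
        sig[(at + 1L):(at + len), ch] <- sig[(at + 1L):(at + len), ch] + pulse
      }
    } else if (kind[i] == "step") {
      # electrode-pop scale (must survive the 0.5-40 Hz band-pass),
      # contained in the middle half of the epoch so both transitions
      # stay inside the corrupted span
      at <- s0 + sample.int(fs %/% 8L, 1L) + fs %/% 4L
      span <- (at + 1L):(at + fs %/% 4L)
      for (ch in sample(1:9, 3L)) {
        sig[span, ch] <- sig[span, ch] + 400
      }
    }
  }
  out$signals <- sig
  attr(out, "corrupted_epochs") <- bad
  attr(out, "artifact_types") <- kind
  attr(out, "truth") <- attr(eeg, "truth")
  out
}

#' Flatten one channel over a fraction of the recording
#'
#' Emulates a disconnected electrode: the chosen channel holds a constant
#' value over a contiguous span covering `fraction` of the duration.
#'
#' @param eeg an `eeg_record`.
#' @param channel label or index.
#' @param fraction fraction of total duration to flatten.
#' @export
flatten_channel <- function(eeg, channel, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(eeg$signals)
  len <- round(fraction * n)
  if (len == 0) return(eeg)
  ch <- if (is.character(channel)) match(channel, eeg$labels) else channel
  start <- max(1L, n %/% 4L)
  span <- start:min(n, start + len - 1L)
  eeg$signals[span, ch] <- eeg$signals[start, ch]
  eeg
}
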