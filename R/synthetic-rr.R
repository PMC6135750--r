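# Generative model for inter-beat (RR) series and the ECG waveform built
# from them. The RR model is deliberately simple -- a mean level plus two
# sinusoidal modulations (0.1 Hz "LF", 0.25 Hz "HF") plus white jitter --
# because every downstream HRV estimator has a closed-form expectation on
# it, which is what makes the pipeline testable.

#' Construct an RR series object
#'
#' @param beat_times_ms strictly increasing beat times, ms.
#' @param corrected_flags optional per-interval logical flags marking
#'   intervals replaced by artifact correction.
#' @return object of class `rr_series` with fields `intervals_ms`,
#'   `beat_times_ms`, `corrected_flags`.
#' @export
rr_series <- function(beat_times_ms, corrected_flags = NULL) {
  if (length(beat_times_ms) > 1 && any(diff(beat_times_ms) <= 0)) {
    reject("beat times must be strictly increasing", "affectpipe_bad_input")
  }
  intervals <- diff(beat_times_ms)
  structure(list(
    intervals_ms = intervals,
    beat_times_ms = beat_times_ms,
    corrected_flags = corrected_flags %||% rep(FALSE, length(intervals))
  ), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms, %d corrected\n",
              length(x$intervals_ms),
              if (length(x$intervals_ms)) mean(x$intervals_ms) else NA,
              sum(x$corrected_flags)))
  invisible(x)
}

#' Generate a synthetic RR interval series for one stimulus window
#'
#' The instantaneous RR interval follows
#' `RR(t) = rr_mean + lf_amp sin(2 pi 0.1 t) + hf_amp sin(2 pi 0.25 t) + e`,
#' with `e ~ N(0, rr_jitter_ms^2)`. For a high-arousal window the LF depth
#' is multiplied by `sqrt(arousal_effect)` and the HF depth divided by it,
#' shifting sympatho-vagal balance (the LF/HF power ratio) by a factor of
#' `arousal_effect^2` while leaving total modulation power unchanged.
#'
#' @param cfg a [synthetic_config()].
#' @param arousal_high logical label for the window.
#' @return `rr_series` with attribute `truth`: the effective modulation
#'   parameters (lf_amp, hf_amp, rr_mean, jitter) used.
#' @export
generate_rr_series <- function(cfg, arousal_high = FALSE) {
  if (cfg$window_s < 60) {
    reject("window_s must be >= 60 s for HRV analysis",
           "affectpipe_bad_config")
  }
  if (cfg$rr_mean_ms < 500 || cfg$rr_mean_ms > 1200) {
    reject("rr_mean_ms must lie in [500, 1200] ms", "affectpipe_bad_config")
  }
  lf <- cfg$lf_amp_ms
  hf <- cfg$hf_amp_ms
  if (isTRUE(arousal_high)) {
    lf <- lf * sqrt(cfg$arousal_effect)
    hf <- hf / sqrt(cfg$arousal_effect)
  }
  window_ms <- cfg$window_s * 1000
  beats <- numeric(ceiling(window_ms / cfg$rr_mean_ms * 1.5) + 2L)
  beats[1] <- 0
  k <- 1L
  while (beats[k] < window_ms) {
    t_s <- beats[k] / 1000
    rr <- cfg$rr_mean_ms +
      lf * sin(2 * pi * 0.1 * t_s) +
      hf * sin(2 * pi * 0.25 * t_s) +
      if (cfg$rr_jitter_ms > 0) stats::rnorm(1, 0, cfg$rr_jitter_ms) else 0
    rr <- max(rr, 250)                 # physiological floor
    k <- k + 1L
    beats[k] <- beats[k - 1L] + rr
  }
  out <- rr_series(beats[seq_len(k)])
  attr(out, "truth") <- list(rr_mean_ms = cfg$rr_mean_ms, lf_amp_ms = lf,
                             hf_amp_ms = hf, jitter_ms = cfg$rr_jitter_ms,
                             lf_hz = 0.1, hf_hz = 0.25)
  out
}

#' Construct an ECG record object
#'
#' @param samples waveform in uV.
#' @param fs sampling rate, Hz.
#' @export
ecg_record <- function(samples, fs) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = length(samples) / fs),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s at %g Hz (%d samples)\n",
              x$duration_s, x$fs, length(x$samples)))
  invisible(x)
}

# 80 ms Mexican-hat (Ricker) QRS-like template, peak-normalized.
qrs_template <- function(fs, width_ms = 80, sigma_ms = 9) {
  half <- round(width_ms / 2 * fs / 1000)
  t_ms <- (-half:half) * 1000 / fs
  a <- (t_ms / sigma_ms)^2
  (1 - a) * exp(-a / 2)
}

#' Synthesize an ECG waveform from an RR series
#'
#' Places a fixed 80 ms Mexican-hat QRS-like template of amplitude
#' `r_amp_uv` at each beat time, then adds slow sinusoidal baseline wander
#' and white measurement noise. P and T waves are deliberately absent: the
#' template exercises the full QRS detection chain without anatomical
#' realism.
#'
#' @param rr an `rr_series`.
#' @param fs sampling rate, Hz (>= 128).
#' @param noise_sd white-noise sd, uV.
#' @param wander_uv baseline-wander amplitude, uV (0.2 Hz sinusoid).
#' @param r_amp_uv R-peak amplitude, uV.
#' @param duration_s optional total duration; default covers the last beat
#'   plus one template.
#' @return `ecg_record` with attribute `truth_beats`: ground-truth R-peak
#'   sample indices (1-based).
#' @export
generate_ecg <- function(rr, fs, noise_sd = 0, wander_uv = 0,
                         r_amp_uv = 1000, duration_s = NULL) {
  if (fs < 128) reject("fs must be >= 128 Hz", "affectpipe_bad_config")
  tmpl <- qrs_template(fs)
  half <- (length(tmpl) - 1L) %/% 2L
  beats_ms <- rr$beat_times_ms
  if (length(beats_ms) == 0) {
    out <- ecg_record(numeric(0), fs)
    attr(out, "truth_beats") <- integer(0)
    return(out)
  }
  if (length(rr$intervals_ms) && min(rr$intervals_ms) < 1000 * length(tmpl) / fs) {
    reject("beat interval shorter than QRS template length",
           "affectpipe_bad_input")
  }
  dur <- duration_s %||% ((max(beats_ms) / 1000) + length(tmpl) / fs)
  n <- ceiling(dur * fs)
  x <- numeric(n + 2L * half)              # padded so edge beats fit
  idx0 <- round(beats_ms / 1000 * fs) + 1L
  for (i in idx0) {
    span <- (i):(i + 2L * half)            # padded coordinates
    x[span] <- x[span] + r_amp_uv * tmpl
  }
  x <- x[(half + 1L):(half + n)]
  t_s <- (seq_len(n) - 1L) / fs
  if (wander_uv > 0) x <- x + wander_uv * sin(2 * pi * 0.2 * t_s)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  out <- ecg_record(x, fs)
  attr(out, "truth_beats") <- idx0[idx0 <= n]
  out
}
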