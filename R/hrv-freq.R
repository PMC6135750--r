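# Frequency-domain HRV: evenly resampled tachogram + Welch periodogram,
# integrated over the VLF / LF / HF bands.

#' Default HRV spectral band edges (Hz)
#'
#' VLF below 0.04, LF 0.04-0.15, HF 0.15-0.4 (the conventional HF band;
#' edges are arguments of [frequency_domain()] for anyone wanting
#' different limits).
#' @export
HRV_BANDS <- list(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))

#' Frequency-domain HRV features
#'
#' The (detrended, artifact-corrected) RR series is cubic-spline
#' interpolated to an evenly sampled tachogram at `resample_hz`, and a
#' Welch PSD is estimated (Hann taper, `welch_window_s` segments, 50%
#' overlap). Per band: peak frequency, absolute power (ms^2) and
#' percentage of total power; LF and HF additionally in normalized units,
#' i.e. the percentage of total power with the VLF contribution
#' subtracted; plus the LF/HF ratio and the total power.
#'
#' @param rr an `rr_series` (ideally output of [detrend_rr()]) covering
#'   at least 60 s.
#' @param resample_hz tachogram sampling rate (default 4 Hz).
#' @param welch_window_s Welch segment length, s (default 60).
#' @param bands band edges, as [HRV_BANDS].
#' @return named list of spectral features; attribute `vlf_reliable` is
#'   FALSE when the window is too short (< 300 s) to resolve the VLF band
#'   trustworthily, in which case the VLF numbers are indicative only.
#' @export
frequency_domain <- function(rr, resample_hz = 4, welch_window_s = 60,
                             bands = HRV_BANDS) {
  t_ms <- rr$beat_times_ms
  x <- rr$intervals_ms
  if (length(x) < 10) reject("too few intervals", "affectpipe_bad_input")
  span_s <- (max(t_ms) - min(t_ms)) / 1000
  if (span_s < 60) {
    reject("window must cover >= 60 s for spectral analysis",
           "affectpipe_bad_input")
  }
  # RR value attributed to the time of the terminating beat
  tt <- t_ms[-1] / 1000
  grid <- seq(min(tt), max(tt), by = 1 / resample_hz)
  tacho <- stats::spline(tt, x, xout = grid, method = "natural")$y
  nseg <- min(length(tacho), round(welch_window_s * resample_hz))
  w <- welch_psd(tacho, fs = resample_hz, nperseg = nseg)
  feat <- list()
  for (b in names(bands)) {
    e <- bands[[b]]
    idx <- which(w$freq >= e[1] & w$freq <= e[2] & w$freq > 0)
    feat[[paste0(b, "_peak")]] <-
      if (length(idx)) w$freq[idx[which.max(w$psd[idx])]] else NA_real_
    feat[[paste0(b, "_power")]] <- band_power_psd(w$freq, w$psd, e[1], e[2])
  }
  total <- feat$vlf_power + feat$lf_power + feat$hf_power
  nonvlf <- total - feat$vlf_power
  out <- list(
    vlf_peak = feat$vlf_peak, lf_peak = feat$lf_peak, hf_peak = feat$hf_peak,
    vlf_power = feat$vlf_power, lf_power = feat$lf_power,
    hf_power = feat$hf_power,
    vlf_pct = 100 * feat$vlf_power / total,
    lf_pct = 100 * feat$lf_power / total,
    hf_pct = 100 * feat$hf_power / total,
    lf_nu = 100 * feat$lf_power / nonvlf,
    hf_nu = 100 * feat$hf_power / nonvlf,
    lf_hf = feat$lf_power / feat$hf_power,
    total_power = total
  )
  attr(out, "vlf_reliable") <- span_s >= 300
  out
}
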