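# One call from raw ECG to the named 26-feature HRV block.

#' Names of the 26 HRV features, in canonical order
#' @export
HRV_FEATURE_NAMES <- c(
  "mean_rr", "std_rr", "rmssd", "pnn50", "tri_index", "tinn",
  "vlf_peak", "lf_peak", "hf_peak",
  "vlf_power", "vlf_pct", "lf_power", "lf_pct", "lf_nu",
  "hf_power", "hf_pct", "hf_nu", "lf_hf", "total_power",
  "sd1", "sd2", "apen", "sampen", "dfa_a1", "dfa_a2", "d2"
)

#' Full HRV feature vector for one stimulus window
#'
#' Runs the complete chain -- Pan-Tompkins beat detection, threshold
#' artifact correction, smoothness-priors detrending -- then computes the
#' time-domain, frequency-domain and nonlinear features. Time-domain and
#' nonlinear features are computed on the corrected series with the slow
#' trend removed but the mean level restored (so `mean_rr` is the true
#' mean interval); spectral features are computed on the zero-mean
#' detrended residual.
#'
#' @param ecg an `ecg_record` covering one stimulus window (~90 s).
#' @param correct_threshold_ms artifact-correction threshold (ms).
#' @param lambda smoothness-priors regularization.
#' @param apen_m,apen_r_coef entropy embedding dimension and tolerance
#'   coefficient (r = coef * SD).
#' @return named numeric vector of length 26 ([HRV_FEATURE_NAMES]).
#'   Features whose preconditions the window cannot satisfy (DFA alpha2
#'   below 130 beats, D2 below 200 beats, undefined SampEn) are `NA`.
#'   Upstream rejections (undetectable beats, unusable windows)
#'   propagate as classed conditions.
#' @export
hrv_feature_vector <- function(ecg, correct_threshold_ms = 250,
                               lambda = 500, apen_m = 2L,
                               apen_r_coef = 0.2) {
  rr <- detect_r_peaks(ecg)
  if (isTRUE(attr(rr, "undetectable"))) {
    reject("no QRS complexes detectable", "affectpipe_no_beats")
  }
  rr <- correct_rr_artifacts(rr, threshold_ms = correct_threshold_ms)
  det <- detrend_rr(rr, lambda = lambda)
  stationary <- det$intervals_ms + det$mean_ms   # trend-free, true mean
  td <- time_domain(stationary)
  fd <- frequency_domain(det)
  pc <- poincare(stationary)
  r_tol <- apen_r_coef * stats::sd(stationary)
  ap <- tryCatch(approximate_entropy(stationary, m = apen_m, r = r_tol),
                 affectpipe_rejection = function(e) NA_real_)
  se <- tryCatch(sample_entropy(stationary, m = apen_m, r = r_tol),
                 affectpipe_rejection = function(e) NA_real_)
  df <- tryCatch(dfa(stationary),
                 affectpipe_rejection = function(e)
                   list(alpha1 = NA_real_, alpha2 = NA_real_))
  cd <- correlation_dimension(stationary)
  out <- c(
    mean_rr = td$mean_rr, std_rr = td$std_rr, rmssd = td$rmssd,
    pnn50 = td$pnn50, tri_index = td$tri_index, tinn = td$tinn,
    vlf_peak = fd$vlf_peak, lf_peak = fd$lf_peak, hf_peak = fd$hf_peak,
    vlf_power = fd$vlf_power, vlf_pct = fd$vlf_pct,
    lf_power = fd$lf_power, lf_pct = fd$lf_pct, lf_nu = fd$lf_nu,
    hf_power = fd$hf_power, hf_pct = fd$hf_pct, hf_nu = fd$hf_nu,
    lf_hf = fd$lf_hf, total_power = fd$total_power,
    sd1 = pc$sd1, sd2 = pc$sd2,
    apen = ap, sampen = se,
    dfa_a1 = df$alpha1, dfa_a2 = df$alpha2, d2 = cd$d2
  )
  stopifnot(identical(names(out), HRV_FEATURE_NAMES))
  attr(out, "vlf_reliable") <- attr(fd, "vlf_reliable")
  attr(out, "n_corrected") <- attr(rr, "n_corrected")
  out
}
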