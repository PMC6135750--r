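# Shared signal-processing primitives. Welch averaging and the analytic
# signal are built directly on stats::fft; filters come from the `signal`
# package (zero-phase Butterworth via filtfilt).

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann taper. Returns a one-sided
#' density so that `sum(psd) * df` approximates the signal variance
#' (power of a sinusoid of amplitude A integrates to A^2/2).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default: `min(length(x), 256)`).
#' @param noverlap overlap in samples (default: 50% of `nperseg`).
#' @param demean subtract the segment mean before tapering (default TRUE).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 256L),
                      noverlap = nperseg %/% 2L, demean = TRUE) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  noverlap <- min(as.integer(noverlap), nperseg - 1L)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- hann_window(nperseg)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    seg * win
  }, numeric(nperseg))
  spec <- Mod(stats::mvfft(segs))^2
  scale <- fs * sum(win^2)
  nf <- nperseg %/% 2L + 1L
  psd <- rowMeans(spec)[seq_len(nf)] / scale
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * dbl)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Band power from a PSD by trapezoidal integration
#'
#' @param freq,psd as returned by [welch_psd()].
#' @param lo,hi band edges in Hz (lo exclusive convention not applied;
#'   bins with `lo <= f <= hi` are integrated).
#' @return power in squared signal units.
#' @export
band_power_psd <- function(freq, psd, lo, hi) {
  idx <- which(freq >= lo & freq <= hi)
  if (length(idx) < 2L) {
    if (length(idx) == 1L) {
      df <- if (length(freq) > 1L) freq[2] - freq[1] else 1
      return(psd[idx] * df)
    }
    return(0)
  }
  sum(diff(freq[idx]) * (psd[idx][-1] + psd[idx][-length(idx)]) / 2)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector (or matrix, column-wise).
#' @return complex vector/matrix whose argument is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    h <- hilbert_gain(n)
    return(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
  }
  n <- length(x)
  h <- hilbert_gain(n)
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

hilbert_gain <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  h
}

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`),
#' so the effective magnitude response is 8th order with zero phase lag.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz. `lo = 0` gives a low-pass, `hi = Inf` a
#'   high-pass.
#' @param order filter order per pass (default 4).
#' @export
bandpass_filter <- function(x, fs, lo, hi, order = 4L) {
  nyq <- fs / 2
  stopifnot(lo < hi, hi > 0)
  flt <- if (lo <= 0) {
    signal::butter(order, hi / nyq, type = "low")
  } else if (!is.finite(hi) || hi >= nyq) {
    signal::butter(order, lo / nyq, type = "high")
  } else {
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  }
  if (is.matrix(x)) {
    apply(x, 2L, function(col) signal::filtfilt(flt, col))
  } else {
    signal::filtfilt(flt, x)
  }
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with a 1/sqrt(f)
#' amplitude profile and rescaled to unit variance.
#'
#' @param n number of samples.
#' @return numeric vector, mean ~0, sd 1.
#' @export
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # mirror so conjugate symmetry survives
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# Classed rejection conditions: every rule-based rejection in the pipeline
# raises one of these so callers (and tests) can distinguish a scientific
# rejection from a programming error.
reject <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "affectpipe_rejection", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (s == 0 || is.na(s)) return(rep(0, length(x)))
  (x - med) / s
}
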