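# From raw ECG to a clean RR series: Pan-Tompkins beat detection,
# threshold-based ectopic/missed-beat correction against a local median,
# and smoothness-priors detrending of the interval series.

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic chain: zero-phase band-pass around the QRS energy (5-15 Hz),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' adaptive dual-threshold peak picking with running signal/noise levels
#' and a search-back pass that rescues beats missed for longer than 1.66
#' times the running RR average. Peak positions are refined to the
#' band-passed waveform maximum near each integration peak.
#'
#' @param ecg an `ecg_record` (>= 10 s at >= 128 Hz).
#' @param refractory_ms minimum separation between beats, ms.
#' @return an `rr_series`; a signal in which no QRS can be found yields an
#'   empty series with attribute `undetectable = TRUE`.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 200) {
  if (ecg$duration_s < 10) {
    reject("ECG shorter than 10 s", "affectpipe_bad_input")
  }
  if (ecg$fs < 128) reject("fs must be >= 128 Hz", "affectpipe_bad_input")
  fs <- ecg$fs
  x <- ecg$samples
  empty <- function() {
    out <- rr_series(numeric(0))
    attr(out, "undetectable") <- TRUE
    out
  }
  if (stats::sd(x) == 0) return(empty())
  bp <- bandpass_filter(x, fs, 5, 15, order = 3L)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2L)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  win <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 1L))
  mwi[is.na(mwi)] <- 0
  refr <- round(refractory_ms / 1000 * fs)
  cand <- local_maxima(mwi, refr)
  if (length(cand) == 0) return(empty())

  # adaptive thresholds, initialized from the first 2 s
  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- max(init) / 3
  npki <- mean(init) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  beats <- integer(0)
  rr_avg <- NA_real_
  missed_buf <- integer(0)
  for (p in cand) {
    if (mwi[p] > thr1) {
      beats <- c(beats, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      missed_buf <- integer(0)
      if (length(beats) >= 2) {
        rrs <- diff(utils::tail(beats, 9L))
        rr_avg <- mean(rrs)
      }
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      missed_buf <- c(missed_buf, p)
      # search-back: too long since the last beat -> take the best skipped
      # candidate that clears the lower threshold
      if (length(beats) > 0 && !is.na(rr_avg) &&
          (p - beats[length(beats)]) > 1.66 * rr_avg) {
        ok <- missed_buf[mwi[missed_buf] > 0.5 * thr1]
        if (length(ok)) {
          b <- ok[which.max(mwi[ok])]
          beats <- sort(c(beats, b))
          spki <- 0.25 * mwi[b] + 0.75 * spki
          missed_buf <- integer(0)
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(beats) == 0) return(empty())
  # refine to the band-passed peak (the MWI peak lags the R wave)
  look <- round(0.15 * fs)
  refined <- vapply(beats, function(p) {
    lo <- max(1L, p - look)
    hi <- min(length(bp), p + round(0.05 * fs))
    lo + which.max(bp[lo:hi]) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  refined <- refined[c(TRUE, diff(refined) > refr)]
  out <- rr_series(1000 * (refined - 1L) / fs)
  attr(out, "peak_indices") <- refined
  out
}

local_maxima <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_pk) == 0) return(integer(0))
  # greedy thinning by prominence order would reorder time; keep temporal
  # order and let the adaptive thresholds do the rest, only enforcing a
  # hard refractory spacing
  keep <- integer(0)
  last <- -Inf
  for (p in is_pk) {
    if (p - last >= min_dist) {
      keep <- c(keep, p)
      last <- p
    } else if (x[p] > x[keep[length(keep)]]) {
      keep[length(keep)] <- p
      last <- p
    }
  }
  keep
}

#' Correct RR artifacts against a local median
#'
#' An interval deviating from the 11-beat running median by more than
#' `threshold_ms` is flagged and replaced by cubic-spline interpolation
#' over the unflagged neighbors. If more than `max_fraction` of intervals
#' are flagged the window is rejected as unusable.
#'
#' @param rr an `rr_series`.
#' @param threshold_ms deviation threshold, ms (default 250).
#' @param max_fraction maximum tolerable flagged fraction (default 0.2).
#' @return corrected `rr_series` with `corrected_flags` set and attribute
#'   `n_corrected`.
#' @export
correct_rr_artifacts <- function(rr, threshold_ms = 250, max_fraction = 0.2) {
  if (threshold_ms <= 0) {
    reject("threshold_ms must be positive", "affectpipe_bad_config")
  }
  x <- rr$intervals_ms
  n <- length(x)
  if (n < 3) return(rr)
  med <- stats::runmed(x, k = min(11L, n - (1 - n %% 2)), endrule = "median")
  bad <- abs(x - med) > threshold_ms
  if (mean(bad) > max_fraction) {
    reject(sprintf("%.0f%% of intervals flagged; window unusable",
                   100 * mean(bad)), "affectpipe_unusable_window")
  }
  if (any(bad) && sum(!bad) >= 4) {
    x[bad] <- stats::spline(x = which(!bad), y = x[!bad],
                            xout = which(bad), method = "natural")$y
  }
  out <- rr
  out$intervals_ms <- x
  out$corrected_flags <- bad
  attr(out, "n_corrected") <- sum(bad)
  out
}

#' Smoothness-priors detrending of an RR series
#'
#' Removes the slow trend `(I + lambda^2 D2' D2)^{-1} z` (a second-order
#' difference-regularized smoother acting as a time-varying high-pass
#' filter; lambda = 500 corresponds to a cutoff near 0.035 Hz at typical
#' beat rates) and returns the zero-mean residual, keeping the trend as
#' an attribute.
#'
#' @param rr an `rr_series` with >= 10 intervals.
#' @param lambda regularization parameter (default 500).
#' @return `rr_series` (class also `rr_detrended`) whose `intervals_ms`
#'   is the residual; attribute `trend_ms` holds the removed trend.
#' @export
detrend_rr <- function(rr, lambda = 500) {
  z <- rr$intervals_ms
  n <- length(z)
  if (n < 10) reject("need >= 10 intervals to detrend", "affectpipe_bad_input")
  D2 <- diff(diag(n), differences = 2L)
  trend <- solve(diag(n) + lambda^2 * crossprod(D2), z)
  structure(list(intervals_ms = as.numeric(z - trend),
                 beat_times_ms = rr$beat_times_ms,
                 corrected_flags = rr$corrected_flags,
                 mean_ms = mean(z)),
            trend_ms = as.numeric(trend),
            class = c("rr_detrended", "rr_series"))
}
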