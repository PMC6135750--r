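# Time-domain and Poincare HRV descriptors.

#' Time-domain HRV features
#'
#' Mean and sample standard deviation of RR, RMSSD, pNN50 (percentage of
#' successive-difference magnitudes strictly greater than 50 ms), the RR
#' triangular index (sample count divided by the modal bin count of the
#' 1/128 s histogram) and TINN (baseline width of the best-fitting
#' triangle over that histogram).
#'
#' @param rr an `rr_series` (or numeric vector of intervals, ms) with at
#'   least 2 intervals.
#' @return named list: `mean_rr`, `std_rr`, `rmssd`, `pnn50`,
#'   `tri_index`, `tinn`.
#' @export
time_domain <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals_ms else as.numeric(rr)
  if (length(x) < 2) {
    reject("need >= 2 intervals for time-domain features",
           "affectpipe_bad_input")
  }
  d <- diff(x)
  hist_bin <- 1000 / 128                      # standard 1/128 s bin width
  breaks <- seq(floor(min(x) / hist_bin) * hist_bin,
                ceiling(max(x) / hist_bin) * hist_bin + hist_bin,
                by = hist_bin)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  list(
    mean_rr = mean(x),
    std_rr = stats::sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    tri_index = length(x) / max(counts),
    tinn = tinn_width(counts, breaks)
  )
}

# Triangular interpolation of the RR histogram: find baseline points N
# (left) and M (right) around the mode minimizing squared error of the
# triangle with apex at the mode; TINN = M - N.
tinn_width <- function(counts, breaks) {
  k <- length(counts)
  centers <- (breaks[-1] + breaks[-(k + 1)]) / 2
  if (k == 1) return(breaks[2] - breaks[1])
  mode_i <- which.max(counts)
  peak <- counts[mode_i]
  best <- c(err = Inf, n = 1, m = k)
  for (n_i in seq_len(mode_i)) {
    for (m_i in mode_i:k) {
      tri <- numeric(k)
      if (mode_i > n_i) {
        left <- n_i:mode_i
        tri[left] <- peak * (left - n_i) / (mode_i - n_i)
      } else tri[mode_i] <- peak
      if (m_i > mode_i) {
        right <- mode_i:m_i
        tri[right] <- peak * (m_i - right) / (m_i - mode_i)
      }
      tri[mode_i] <- peak
      err <- sum((counts - tri)^2)
      if (err < best["err"]) best <- c(err = err, n = n_i, m = m_i)
    }
  }
  centers[best[["m"]]] - centers[best[["n"]]]
}

#' Poincare plot dispersions SD1 and SD2
#'
#' SD1 (minor axis, fast beat-to-beat variability) is the dispersion of
#' successive differences scaled by 1/sqrt(2); SD2 (major axis, longer
#' term variability) follows from the exact decomposition
#' `SD1^2 + SD2^2 = 2 SDNN^2`.
#'
#' @param rr an `rr_series` or numeric vector (>= 3 intervals).
#' @return list with `sd1` and `sd2` (ms).
#' @export
poincare <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals_ms else as.numeric(rr)
  if (length(x) < 3) reject("need >= 3 intervals", "affectpipe_bad_input")
  sd1 <- stats::sd(diff(x)) / sqrt(2)
  sd2 <- sqrt(max(0, 2 * stats::sd(x)^2 - sd1^2))
  list(sd1 = sd1, sd2 = sd2)
}
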