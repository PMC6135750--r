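# Nonlinear HRV descriptors: approximate and sample entropy, detrended
# fluctuation analysis, and the Grassberger-Procaccia correlation
# dimension. All operate on the interval series as a generic time series.

as_intervals <- function(rr) {
  if (inherits(rr, "rr_series")) rr$intervals_ms else as.numeric(rr)
}

# Chebyshev (max-norm) distance matrix between m-length templates of x.
template_dist <- function(x, m) {
  n <- length(x) - m + 1L
  d <- abs(outer(x[1:n], x[1:n], "-"))
  if (m > 1) {
    for (k in 2:m) {
      dk <- abs(outer(x[k:(k + n - 1L)], x[k:(k + n - 1L)], "-"))
      d <- pmax(d, dk)
    }
  }
  d
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where Phi_m is the mean log
#' fraction of templates (self-matches included) within Chebyshev
#' distance r. Lower values indicate more regular dynamics.
#'
#' @param rr `rr_series` or numeric vector (>= 100 samples).
#' @param m embedding dimension (default 2).
#' @param r tolerance; defaults to 0.2 times the series SD.
#' @return entropy in nats.
#' @export
approximate_entropy <- function(rr, m = 2L, r = NULL) {
  x <- as_intervals(rr)
  n <- length(x)
  if (n < 100) reject("need >= 100 samples", "affectpipe_bad_input")
  if (stats::sd(x) == 0) return(0)    # every template matches every other
  r <- r %||% (0.2 * stats::sd(x))
  if (r <= 0) reject("tolerance r must be positive on non-constant data",
                     "affectpipe_bad_input")
  phi <- function(mm) {
    d <- template_dist(x, mm)
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) with B the number of m-template pairs (i < j,
#' self-matches excluded) within tolerance r and A the corresponding
#' (m+1)-template count.
#'
#' @inheritParams approximate_entropy
#' @return entropy in nats; if no template pairs match at either length
#'   the statistic is undefined and a rejection condition is raised.
#' @export
sample_entropy <- function(rr, m = 2L, r = NULL) {
  x <- as_intervals(rr)
  n <- length(x)
  if (n < m + 2L) reject("series too short", "affectpipe_bad_input")
  if (stats::sd(x) == 0) return(0)
  r <- r %||% (0.2 * stats::sd(x))
  count_pairs <- function(mm) {
    d <- template_dist(x, mm)
    # templates of length m and m+1 must be counted over the same number
    # of vectors (N - m) for the standard definition
    keep <- seq_len(length(x) - m)
    d <- d[keep, keep, drop = FALSE]
    (sum(d <= r) - length(keep)) / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0 || A == 0) {
    reject("no matching templates; SampEn undefined",
           "affectpipe_undefined")
  }
  -log(A / B)
}

#' Detrended fluctuation analysis exponents
#'
#' The mean-centered series is integrated; in non-overlapping boxes of
#' size n a least-squares line is removed and the RMS residual F(n)
#' recorded; alpha is the slope of log F(n) versus log n, fitted
#' separately over the short (4-16) and long (16-64) box ranges.
#'
#' @param rr `rr_series` or numeric vector.
#' @param short_range,long_range integer box sizes for alpha1 / alpha2.
#' @return list with `alpha1` and `alpha2`; `alpha2` is `NA` when the
#'   series is shorter than 130 samples (fewer than two boxes at the
#'   largest sizes).
#' @export
dfa <- function(rr, short_range = 4:16, long_range = 16:64) {
  x <- as_intervals(rr)
  n <- length(x)
  if (n < 2 * max(short_range)) {
    reject("series too short for DFA", "affectpipe_bad_input")
  }
  y <- cumsum(x - mean(x))
  fluct <- function(scales) {
    scales <- scales[scales <= n %/% 2L]
    if (length(scales) < 3) return(NULL)
    Fn <- vapply(scales, function(s) {
      nb <- n %/% s
      res2 <- 0
      tt <- seq_len(s)
      for (b in seq_len(nb)) {
        seg <- y[((b - 1L) * s + 1L):(b * s)]
        fit <- stats::lm.fit(cbind(1, tt), seg)
        res2 <- res2 + sum(fit$residuals^2)
      }
      sqrt(res2 / (nb * s))
    }, numeric(1))
    stats::coef(stats::lm(log(Fn) ~ log(scales)))[[2]]
  }
  alpha1 <- fluct(short_range)
  alpha2 <- if (n >= 130) fluct(long_range) else NULL
  list(alpha1 = alpha1 %||% NA_real_, alpha2 = alpha2 %||% NA_real_)
}

#' Grassberger-Procaccia correlation dimension
#'
#' Delay-embeds the series (dimension `m`, unit delay), computes
#' correlation sums C(r) over a log-spaced radius grid (Chebyshev norm,
#' Theiler exclusion window `theiler`), and estimates D2 as the slope of
#' log C versus log r over the scaling region 0.5% < C(r) < 30%. A
#' saturation flag compares the estimate against a lower embedding
#' dimension: stochastic series keep growing with m and are flagged
#' unsaturated.
#'
#' @param rr `rr_series` or numeric vector (>= 200 samples, else `NA`).
#' @param m embedding dimension (default 10).
#' @param theiler temporal exclusion window in samples (default 10).
#' @param n_radii radius grid size.
#' @return list with `d2`, `saturated` (logical) and `n_radii_used`;
#'   `d2 = NA` with reason when no scaling region exists.
#' @export
correlation_dimension <- function(rr, m = 10L, theiler = 10L,
                                  n_radii = 24L) {
  x <- as_intervals(rr)
  if (length(x) < 200) {
    return(list(d2 = NA_real_, saturated = NA, n_radii_used = 0L))
  }
  est <- function(mm) {
    d <- template_dist(x, mm)
    ij <- abs(row(d) - col(d))
    dv <- d[ij > theiler & upper.tri(d)]
    if (length(dv) < 100 || max(dv) == 0) return(NA_real_)
    radii <- exp(seq(log(stats::quantile(dv[dv > 0], 0.01)),
                     log(stats::quantile(dv, 0.975)), length.out = n_radii))
    C <- vapply(radii, function(r) mean(dv <= r), numeric(1))
    use <- which(C > 0.005 & C < 0.30)
    if (length(use) < 3) return(NA_real_)
    stats::coef(stats::lm(log(C[use]) ~ log(radii[use])))[[2]]
  }
  d2 <- est(m)
  if (is.na(d2)) {
    return(list(d2 = NA_real_, saturated = NA, n_radii_used = 0L))
  }
  d2_lo <- est(max(2L, m - 4L))
  saturated <- !is.na(d2_lo) && abs(d2 - d2_lo) < 0.1 * max(d2, 1)
  list(d2 = d2, saturated = saturated, n_radii_used = n_radii)
}
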