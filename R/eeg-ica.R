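# Infomax ICA and the artifact-removal hook. The unmixing matrix is
# estimated by natural-gradient infomax (logistic nonlinearity, suited to
# super-Gaussian sources such as blinks) on the whitened data.

#' Natural-gradient infomax ICA
#'
#' @param X numeric matrix, channels x samples (will be row-centered).
#' @param max_iter iteration cap.
#' @param lr initial learning rate (annealed when the update overshoots).
#' @param tol convergence tolerance on the relative update norm.
#' @return list with `unmixing` (k x channels), `mixing` (channels x k),
#'   `sources` (k x samples), `converged` logical.
#' @export
infomax_ica <- function(X, max_iter = 400L, lr = 0.05, tol = 1e-5) {
  k <- nrow(X)
  n <- ncol(X)
  X <- X - rowMeans(X)
  cv <- tcrossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  sphere <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
  Xw <- sphere %*% X
  kk <- nrow(Xw)
  W <- diag(kk)
  I <- diag(kk)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- W %*% Xw
    G <- (I - 2 * tanh(Y) %*% t(Y) / n) %*% W   # natural gradient
    W_new <- W + lr * G
    delta <- sum(abs(lr * G)) / sum(abs(W))
    if (!all(is.finite(W_new))) {               # overshoot: restart smaller
      lr <- lr / 2
      W <- diag(kk)
      next
    }
    W <- W_new
    if (it > 100) lr <- lr * 0.97               # annealing forces settling
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  unmixing <- W %*% sphere
  mixing <- tryCatch(solve(unmixing), error = function(e) MASS_ginv(unmixing))
  list(unmixing = unmixing, mixing = mixing,
       sources = unmixing %*% X, converged = converged)
}

# Moore-Penrose pseudoinverse (tiny local implementation; only reached
# when the unmixing matrix is numerically singular).
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Remove ICA artifact components from epoched EEG
#'
#' Fits infomax ICA on the concatenated retained epochs (9 components),
#' flags artifact components either from an explicit `mask` (the
#' expert-input path) or by the automatic heuristic -- a component is
#' flagged when its activation kurtosis is a robust-z outlier (> 5) or
#' when it is both low-frequency dominated (> 25% of its power below
#' 4 Hz; genuinely oscillatory components sit near 2% after the 0.5 Hz
#' high-pass, while blinks retain a large share) and frontally dominated
#' (> half of its scalp-map energy on Fz/F3/F4) -- zeroes them, and
#' reconstructs the channel data. If more
#' than `max_affected` of all epochs were artifact-flagged upstream the
#' subject is rejected outright.
#'
#' @param ep an `epoched_eeg` with >= 30 retained epochs.
#' @param policy "auto" or "manual".
#' @param mask logical vector over the 9 components (manual policy).
#' @param max_affected rejected-epoch fraction above which the subject is
#'   rejected (default 1/3).
#' @return cleaned `epoched_eeg`; attributes `ica_flagged` (component
#'   indices removed) and `ica_converged`. On non-convergence the input
#'   is returned unchanged with attribute `ica_downgraded = TRUE` and a
#'   warning.
#' @export
remove_ica_artifacts <- function(ep, policy = c("auto", "manual"),
                                 mask = NULL, max_affected = 1 / 3) {
  policy <- match.arg(policy)
  frac_bad <- mean(ep$rejected)
  if (frac_bad > max_affected) {
    reject(sprintf("%.0f%% of epochs artifact-affected; subject rejected",
                   100 * frac_bad), "affectpipe_subject_rejected")
  }
  keep <- which(!ep$rejected)
  if (length(keep) < 30) {
    reject("need >= 30 retained epochs for stable ICA",
           "affectpipe_bad_input")
  }
  fs <- ep$fs
  # channels x samples concatenation of retained epochs
  X <- matrix(0, 9L, length(keep) * fs)
  for (i in seq_along(keep)) {
    X[, ((i - 1L) * fs + 1L):(i * fs)] <- ep$epochs[keep[i], , ]
  }
  fit <- infomax_ica(X)
  if (!fit$converged) {
    warning("infomax ICA did not converge; continuing without ICA cleaning")
    attr(ep, "ica_downgraded") <- TRUE
    return(ep)
  }
  k <- nrow(fit$sources)
  flagged <- if (policy == "manual") {
    which(rep_len(mask %||% logical(k), k))
  } else {
    auto_flag_components(fit, fs, ep$labels)
  }
  attr(ep, "ica_flagged") <- flagged
  attr(ep, "ica_converged") <- TRUE
  if (length(flagged) == 0) return(ep)
  S <- fit$sources
  S[flagged, ] <- 0
  Xc <- fit$mixing %*% S + rowMeans(X)      # restore channel means
  for (i in seq_along(keep)) {
    ep$epochs[keep[i], , ] <- Xc[, ((i - 1L) * fs + 1L):(i * fs)]
  }
  ep
}

auto_flag_components <- function(fit, fs, labels,
                                 kurt_z = 5, lowfreq_frac = 0.25,
                                 frontal_frac = 0.5) {
  k <- nrow(fit$sources)
  kz <- robust_z(apply(fit$sources, 1L, excess_kurtosis))
  frontal <- labels %in% c("Fz", "F3", "F4")
  flags <- logical(k)
  for (i in seq_len(k)) {
    w <- welch_psd(fit$sources[i, ], fs,
                   nperseg = min(ncol(fit$sources), 2L * fs))
    p_low <- band_power_psd(w$freq, w$psd, 0, 4)
    p_tot <- band_power_psd(w$freq, w$psd, 0, fs / 2)
    map <- fit$mixing[, i]^2
    front_dom <- sum(map[frontal]) / sum(map)
    flags[i] <- (abs(kz[i]) > kurt_z) ||
      (p_tot > 0 && p_low / p_tot > lowfreq_frac && front_dom > frontal_frac)
  }
  which(flags)
}
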