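# EEG preprocessing chain: channel QC (kurtosis + flatness), neighbor
# interpolation of a single bad channel, baseline removal + 0.5-40 Hz
# zero-phase band-pass, 1 s epoching with rule-based rejection, and the
# infomax-ICA artifact-removal hook (eeg-ica.R).

# Schematic 2D positions of the 9-channel 10-20 montage, used for
# inverse-distance neighbor interpolation.
EEG_POSITIONS <- matrix(c(
   0.0,  0.45,   # Fz
  -0.4,  0.45,   # F3
   0.4,  0.45,   # F4
   0.0,  0.0,    # Cz
  -0.4,  0.0,    # C3
   0.4,  0.0,    # C4
   0.0, -0.5,    # POz
  -0.4, -0.45,   # P3
   0.4, -0.45    # P4
), ncol = 2, byrow = TRUE,
  dimnames = list(c("Fz","F3","F4","Cz","C3","C4","POz","P3","P4"),
                  c("x", "y")))

#' Identify corrupted EEG channels
#'
#' A channel is corrupted if (a) its excess kurtosis is an outlier among
#' the nine channels (robust z-score beyond `kurt_z`), or (b) it is flat
#' (runs of near-identical samples) for more than `flat_limit` of the
#' total duration.
#'
#' @param eeg an `eeg_record` (>= 10 s).
#' @param kurt_z robust z-score bound on channel kurtosis (default 5).
#' @param flat_limit maximum tolerated flat fraction (default 0.10).
#' @param flat_eps successive-difference magnitude below which samples
#'   count as flat (uV), runs shorter than 0.1 s ignored.
#' @return data frame (class `channel_qc_report`): per-channel kurtosis
#'   z-score, flat fraction, corrupted flag, and the implied `action`
#'   ("none", "interpolated" or "subject_rejected").
#' @export
detect_corrupted_channels <- function(eeg, kurt_z = 5, flat_limit = 0.10,
                                      flat_eps = 0.01) {
  if (eeg$duration_s < 10) {
    reject("need >= 10 s of signal for channel QC", "affectpipe_bad_input")
  }
  sig <- eeg$signals
  kz <- robust_z(apply(sig, 2L, excess_kurtosis))
  min_run <- round(0.1 * eeg$fs)
  ff <- apply(sig, 2L, function(ch) {
    flat <- abs(diff(ch)) < flat_eps
    r <- rle(flat)
    sum(r$lengths[r$values & r$lengths >= min_run]) / length(ch)
  })
  corrupted <- (abs(kz) > kurt_z) | (ff > flat_limit)
  action <- if (sum(corrupted) == 0) "none"
            else if (sum(corrupted) == 1) "interpolated"
            else "subject_rejected"
  structure(data.frame(channel = eeg$labels, kurtosis_z = kz,
                       flat_fraction = ff, corrupted = corrupted,
                       action = action, row.names = NULL),
            class = c("channel_qc_report", "data.frame"))
}

#' Interpolate one corrupted channel from its neighbors
#'
#' Replaces the bad channel with the inverse-distance-weighted mean of
#' its 10-20 neighbors (schematic montage distances, neighbors within
#' radius 0.7). All other channels are returned untouched. Two or more
#' corrupted channels reject the subject.
#'
#' @param eeg an `eeg_record`.
#' @param bad channel label (or index) to replace; may also be a
#'   `channel_qc_report`, in which case the flagged channel is used and
#'   multiple flags raise the subject-rejection condition.
#' @export
interpolate_channel <- function(eeg, bad) {
  if (inherits(bad, "channel_qc_report")) {
    flagged <- bad$channel[bad$corrupted]
    if (length(flagged) == 0) return(eeg)
    if (length(flagged) > 1) {
      reject(sprintf("%d corrupted channels; subject rejected",
                     length(flagged)), "affectpipe_subject_rejected")
    }
    bad <- flagged
  }
  ch <- if (is.character(bad)) match(bad, eeg$labels) else as.integer(bad)
  if (is.na(ch) || ch < 1 || ch > 9) {
    reject("unknown channel", "affectpipe_bad_input")
  }
  pos <- EEG_POSITIONS[eeg$labels, , drop = FALSE]
  d <- sqrt(rowSums((pos - matrix(pos[ch, ], 9, 2, byrow = TRUE))^2))
  nb <- which(d > 0 & d <= 0.7)
  w <- 1 / d[nb]
  w <- w / sum(w)
  eeg$signals[, ch] <- as.numeric(eeg$signals[, nb, drop = FALSE] %*% w)
  attr(eeg, "interpolated") <- eeg$labels[ch]
  eeg
}

#' Baseline removal and 0.5-40 Hz band-pass
#'
#' Subtracts the per-channel mean, then applies a zero-phase 4th-order
#' Butterworth band-pass between 0.5 and 40 Hz.
#'
#' @param eeg an `eeg_record` with fs >= 100 Hz.
#' @param lo,hi filter band edges, Hz.
#' @export
filter_and_baseline <- function(eeg, lo = 0.5, hi = 40) {
  if (eeg$fs < 100) reject("fs must be >= 100 Hz", "affectpipe_bad_input")
  sig <- sweep(eeg$signals, 2L, colMeans(eeg$signals))
  eeg$signals <- bandpass_filter(sig, eeg$fs, lo, hi)
  colnames(eeg$signals) <- eeg$labels
  eeg
}

#' Cut a filtered record into 1 s epochs and apply rejection rules
#'
#' An epoch is rejected when (a) any channel's kurtosis within the epoch
#' is a robust-z outlier (> `kurt_z`) among that channel's epochs, or
#' (b) strictly more than `max_bad_channels` channels contain a sample
#' exceeding `amp_thr` uV in magnitude or an inter-sample step larger
#' than `grad_thr` uV. Reason codes are retained per epoch.
#'
#' @param eeg a filtered `eeg_record`.
#' @param kurt_z kurtosis robust-z bound (default 5).
#' @param amp_thr absolute amplitude threshold, uV (default 100).
#' @param grad_thr inter-sample gradient threshold, uV (default 70).
#' @param max_bad_channels number of offending channels tolerated before
#'   rejection (default 2: rejection needs more than 2).
#' @return object of class `epoched_eeg`: `epochs` (epoch x channel x
#'   sample array), `rejected` mask, `reasons` (comma-joined codes from
#'   {"kurtosis", "amplitude"}), `fs`, `labels`.
#' @export
epoch_and_reject <- function(eeg, kurt_z = 5, amp_thr = 100,
                             grad_thr = 70, max_bad_channels = 2L) {
  fs <- round(eeg$fs)
  n_ep <- floor(nrow(eeg$signals) / fs)
  if (n_ep < 1) reject("record shorter than one epoch", "affectpipe_bad_input")
  ep <- array(0, dim = c(n_ep, 9L, fs),
              dimnames = list(NULL, eeg$labels, NULL))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- t(eeg$signals[((e - 1L) * fs + 1L):(e * fs), ])
  }
  # rule (b): amplitude / gradient on > max_bad_channels channels
  over <- matrix(FALSE, n_ep, 9L)
  kurt <- matrix(0, n_ep, 9L)
  for (ch in 1:9) {
    seg <- ep[, ch, , drop = TRUE]
    if (n_ep == 1) seg <- matrix(seg, 1L)
    grad <- abs(seg[, -1L, drop = FALSE] - seg[, -ncol(seg), drop = FALSE])
    over[, ch] <- (rowSums(abs(seg) > amp_thr) > 0) |
      (rowSums(grad > grad_thr) > 0)
    ctr <- seg - rowMeans(seg)
    m2 <- rowMeans(ctr^2)
    kurt[, ch] <- ifelse(m2 > 0, rowMeans(ctr^4) / m2^2 - 3, 0)
  }
  amp_bad <- rowSums(over) > max_bad_channels
  kz <- apply(kurt, 2L, robust_z)
  if (n_ep == 1) kz <- matrix(kz, 1L)
  kurt_bad <- rowSums(abs(kz) > kurt_z) > 0
  rejected <- amp_bad | kurt_bad
  reasons <- character(n_ep)
  reasons[kurt_bad] <- "kurtosis"
  reasons[amp_bad] <- ifelse(nzchar(reasons[amp_bad]),
                             "kurtosis,amplitude", "amplitude")
  if (all(rejected)) {
    reject("all epochs rejected; window unusable",
           "affectpipe_unusable_window")
  }
  structure(list(epochs = ep, rejected = rejected, reasons = reasons,
                 fs = fs, labels = eeg$labels, epoch_length_s = 1),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("<epoched_eeg> %d epochs (%d rejected) x 9 ch x %d samples\n",
              length(x$rejected), sum(x$rejected), dim(x$epochs)[3]))
  invisible(x)
}
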