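# Whole-study generator: one ECG + EEG window per subject per stimulus,
# with stimuli cycling through the four quadrants of the arousal x valence
# plane (the circumplex model), and self-assessment scores on the -4..+4
# scale drawn consistently with the quadrant.

#' Generate a complete labeled synthetic dataset
#'
#' Stimuli cycle through the four arousal x valence quadrants (high/neg,
#' high/pos, low/neg, low/pos), so with the default four stimuli per
#' subject the binarized labels are balanced 50/50 in each dimension.
#' Physiological signals are generated from the quadrant's labels;
#' self-assessment scores are quadrant-consistent integers (1..4 for the
#' high/positive pole, -4..0 for the low/negative pole) except for a
#' fraction `ambiguity_rate` drawn at the bipolarization boundary, which
#' emulates ambivalent ratings and yields label noise.
#'
#' @param cfg a [synthetic_config()]; `cfg$seed` makes the dataset
#'   byte-reproducible.
#' @return object of class `affect_dataset`: list with `records` (one per
#'   subject-stimulus, each holding `ecg`, `eeg`, scores and labels),
#'   `manifest` (data frame of ids, scores, labels and ground-truth
#'   parameters) and `cfg`.
#' @export
generate_dataset <- function(cfg) {
  if (cfg$n_subjects < 6) {
    reject("n_subjects must be >= 6", "affectpipe_bad_config")
  }
  set.seed(cfg$seed)
  quadrants <- data.frame(
    arousal_high = c(TRUE, TRUE, FALSE, FALSE),
    valence_positive = c(FALSE, TRUE, FALSE, TRUE)
  )
  records <- list()
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    for (k in seq_len(cfg$stimuli_per_subject)) {
      q <- quadrants[((k - 1L) %% 4L) + 1L, ]
      a_sc <- draw_score(q$arousal_high, cfg$ambiguity_rate)
      v_sc <- draw_score(q$valence_positive, cfg$ambiguity_rate)
      rr <- generate_rr_series(cfg, arousal_high = q$arousal_high)
      ecg <- generate_ecg(rr, cfg$fs, noise_sd = cfg$ecg_noise_sd,
                          wander_uv = cfg$ecg_wander_uv,
                          duration_s = cfg$window_s)
      eeg <- generate_eeg(cfg, arousal_high = q$arousal_high,
                          valence_positive = q$valence_positive)
      if (cfg$artifact_rate > 0) {
        eeg <- inject_artifacts(eeg, cfg$artifact_rate)
      }
      rec <- list(
        subject_id = subject_id, stimulus_id = k,
        arousal_score = a_sc, valence_score = v_sc,
        arousal_label = a_sc > 0L, valence_label = v_sc > 0L,
        quadrant_arousal = q$arousal_high,
        quadrant_valence = q$valence_positive,
        ecg = ecg, eeg = eeg, rr_truth = attr(rr, "truth")
      )
      records[[length(records) + 1L]] <- rec
      tr <- attr(eeg, "truth")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject_id, stimulus = k,
        arousal_score = a_sc, valence_score = v_sc,
        arousal_label = a_sc > 0L, valence_label = v_sc > 0L,
        lf_amp_ms = attr(rr, "truth")$lf_amp_ms,
        hf_amp_ms = attr(rr, "truth")$hf_amp_ms,
        beta_amp_uv = if (is.null(tr)) NA else tr$band_amps[["beta"]],
        kappa = if (is.null(tr)) NA else tr$kappa,
        seed = cfg$seed
      )
    }
  }
  structure(list(records = records,
                 manifest = do.call(rbind, rows),
                 cfg = cfg),
            class = "affect_dataset")
}

draw_score <- function(high, ambiguity_rate) {
  if (ambiguity_rate > 0 && stats::runif(1) < ambiguity_rate) {
    return(sample(0:1, 1L))
  }
  if (high) sample(1:4, 1L, prob = c(2, 3, 3, 2)) else
    sample(-4:0, 1L, prob = c(2, 3, 3, 3, 2))
}

#' @export
print.affect_dataset <- function(x, ...) {
  cat(sprintf("<affect_dataset> %d subjects x %d stimuli (%d windows)\n",
              x$cfg$n_subjects, x$cfg$stimuli_per_subject,
              length(x$records)))
  invisible(x)
}
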