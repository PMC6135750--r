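# End-to-end orchestration: feature extraction over a dataset, the
# train/test + LOSO + RFE learning chain, run configuration, and the
# subject-screening utility.

#' Analysis run configuration
#'
#' Collects every tunable threshold of the chain with the documented
#' defaults. Round-trips losslessly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param target "arousal" or "valence".
#' @param variance_target block-PCA cumulative variance target.
#' @param test_fraction subject fraction held out for the test set.
#' @param grid_n,grid_lo,grid_hi SVM grid: `grid_n` values log-spaced in
#'   `[grid_lo, grid_hi]`, for both cost and gamma.
#' @param cor_threshold RFE correlation-group threshold.
#' @param correct_threshold_ms RR artifact-correction threshold.
#' @param lambda smoothness-priors detrending parameter.
#' @param kurt_z kurtosis robust-z bound (channels, epochs, ICA).
#' @param amp_thr,grad_thr epoch rejection thresholds, uV.
#' @param flat_limit channel flat-fraction limit.
#' @param use_ica run the ICA artifact-removal hook (TRUE) or skip it
#'   (sensible when no artifacts are present, as the hook is then an
#'   identity).
#' @param run_rfe run per-fold SVM-RFE and the rank/accuracy curve
#'   (TRUE); FALSE stops after the grid search.
#' @param seed integer seed for the split.
#' @export
run_config <- function(target = c("arousal", "valence"),
                       variance_target = 0.95, test_fraction = 0.15,
                       grid_n = 15L, grid_lo = 0.1, grid_hi = 1000,
                       cor_threshold = 0.85, correct_threshold_ms = 250,
                       lambda = 500, kurt_z = 5, amp_thr = 100,
                       grad_thr = 70, flat_limit = 0.10,
                       use_ica = TRUE, run_rfe = TRUE, seed = 1L) {
  structure(list(
    target = match.arg(target), variance_target = variance_target,
    test_fraction = test_fraction, grid_n = as.integer(grid_n),
    grid_lo = grid_lo, grid_hi = grid_hi, cor_threshold = cor_threshold,
    correct_threshold_ms = correct_threshold_ms, lambda = lambda,
    kurt_z = kurt_z, amp_thr = amp_thr, grad_thr = grad_thr,
    flat_limit = flat_limit, use_ica = isTRUE(use_ica),
    run_rfe = isTRUE(run_rfe), seed = as.integer(seed)
  ), class = "run_config")
}

#' Extract the full feature table from a dataset
#'
#' Runs, per subject-stimulus window, the HRV chain on the ECG and the
#' preprocessing + feature chain on the EEG (channel QC with single
#' -channel interpolation, 0.5-40 Hz filtering, epoching with rule-based
#' rejection, optional infomax-ICA cleaning, band power, mean phase
#' coherence), and assembles the 206-dimensional feature vector. Windows
#' or subjects hit by a rejection rule are dropped with a message; every
#' decision is recorded in the returned `log` attribute.
#'
#' @param dataset an `affect_dataset` (or list of records of the same
#'   shape).
#' @param config a [run_config()].
#' @return data frame: subject, stimulus, scores, labels, then the 206
#'   feature columns; attribute `log` (character), attribute `blocks`.
#' @export
extract_features <- function(dataset, config = run_config()) {
  records <- dataset$records %||% dataset
  rows <- list()
  logs <- character(0)
  blocks <- NULL
  rejected_subjects <- character(0)
  for (rec in records) {
    if (rec$subject_id %in% rejected_subjects) next
    res <- tryCatch({
      hrv <- hrv_feature_vector(
        rec$ecg, correct_threshold_ms = config$correct_threshold_ms,
        lambda = config$lambda)
      eeg <- rec$eeg
      qc <- detect_corrupted_channels(eeg, kurt_z = config$kurt_z,
                                      flat_limit = config$flat_limit)
      if (any(qc$corrupted)) eeg <- interpolate_channel(eeg, qc)
      eeg <- filter_and_baseline(eeg)
      ep <- epoch_and_reject(eeg, kurt_z = config$kurt_z,
                             amp_thr = config$amp_thr,
                             grad_thr = config$grad_thr)
      if (config$use_ica) {
        ep <- remove_ica_artifacts(ep)
      } else if (mean(ep$rejected) > 1 / 3) {
        reject("more than 33% of epochs artifact-affected",
               "affectpipe_subject_rejected")
      }
      fv <- assemble_feature_vector(hrv, band_power(ep),
                                    mean_phase_coherence(ep))
      list(fv = fv, n_rej = sum(ep$rejected))
    },
    affectpipe_subject_rejected = function(e) e,
    affectpipe_rejection = function(e) e)
    if (inherits(res, "condition")) {
      code <- class(res)[1]
      logs <- c(logs, sprintf("%s stim %s: %s [%s]", rec$subject_id,
                              rec$stimulus_id, conditionMessage(res), code))
      if (inherits(res, "affectpipe_subject_rejected")) {
        rejected_subjects <- c(rejected_subjects, rec$subject_id)
        rows <- rows[vapply(rows, function(r) r$subject != rec$subject_id,
                            logical(1))]
      }
      next
    }
    blocks <- blocks %||% attr(res$fv, "blocks")
    rows[[length(rows) + 1L]] <- c(
      list(subject = rec$subject_id, stimulus = rec$stimulus_id,
           arousal_score = rec$arousal_score,
           valence_score = rec$valence_score,
           arousal_label = rec$arousal_label,
           valence_label = rec$valence_label),
      as.list(res$fv)
    )
  }
  if (length(rows) == 0) {
    reject("no usable windows in dataset", "affectpipe_unusable_window")
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  attr(out, "log") <- logs
  attr(out, "blocks") <- blocks
  out
}

#' Run the full classification pipeline on a feature table
#'
#' Implements the learning chain: subject-wise train/test split,
#' block-wise PCA (fitted on training subjects only), sigmoid C-SVM grid
#' search under LOSO cross-validation with fold-internal median/MAD
#' normalization, per-fold SVM-RFE with correlation bias reduction,
#' median-rank aggregation, the accuracy-versus-rank curve, and final
#' evaluation on the held-out test subjects using the selected feature
#' subset and parameters.
#'
#' @param features feature table from [extract_features()] (or a dataset
#'   / `synthetic_config`, which will be generated and extracted first).
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every intermediate
#'   table (reduced features, per-fold ranks, accuracy curve, fold
#'   predictions, confusion matrices) is written as delimited text, plus
#'   a run log declaring the seed and the configuration hash that
#'   produced them.
#' @return object of class `model_report`: `cv` and `test` evaluation
#'   lists (confusion %, accuracy %, F-score), `best` (C, gamma),
#'   `ranks`, `curve`, `best_k`, `pca` (fitted block PCA), `reduced_dim`,
#'   `test_subjects`, `config`.
#' @export
run_pipeline <- function(features, config = run_config(), out_dir = NULL) {
  if (inherits(features, "synthetic_config")) {
    features <- generate_dataset(features)
  }
  if (inherits(features, "affect_dataset")) {
    features <- extract_features(features, config)
  }
  label_col <- paste0(config$target, "_label")
  y <- features[[label_col]]
  sp <- split_train_test(features, test_fraction = config$test_fraction,
                         seed = config$seed)
  pca <- fit_block_pca(sp$train, variance_target = config$variance_target)
  Xtr <- predict(pca, sp$train)
  Xte <- predict(pca, sp$test)
  ytr <- sp$train[[label_col]]
  yte <- sp$test[[label_col]]
  str_ <- sp$train$subject
  grid <- svm_param_grid(config$grid_n, config$grid_lo, config$grid_hi)
  gs <- grid_search_svm(Xtr, ytr, str_, cost_grid = grid, gamma_grid = grid)

  ranks <- NULL; agg <- NULL; curve <- NULL; best_k <- ncol(Xtr)
  if (config$run_rfe) {
    subs <- unique(str_)
    rank_mat <- matrix(0, length(subs), ncol(Xtr),
                       dimnames = list(subs, colnames(Xtr)))
    for (i in seq_along(subs)) {
      hold <- str_ == subs[i]
      Xf <- normalize_median_mad(Xtr[!hold, , drop = FALSE])
      rank_mat[i, ] <- svm_rfe_cbr(Xf, ytr[!hold], C = gs$C,
                                   gamma = gs$gamma,
                                   cor_threshold = config$cor_threshold)
    }
    agg <- aggregate_ranks(rank_mat)
    curve <- accuracy_vs_rank_curve(Xtr, ytr, str_, agg$feature,
                                    C = gs$C, gamma = gs$gamma)
    best_k <- curve$best_k
    ranks <- rank_mat
  }
  sel <- if (config$run_rfe) agg$feature[seq_len(best_k)] else colnames(Xtr)
  cv <- loso_cv(Xtr, ytr, str_, C = gs$C, gamma = gs$gamma, features = sel)

  Xtr_n <- normalize_median_mad(Xtr[, sel, drop = FALSE])
  Xte_n <- normalize_median_mad(Xtr[, sel, drop = FALSE],
                                Xte[, sel, drop = FALSE])
  final <- fit_svm(Xtr_n, ytr, gs$C, gs$gamma)
  test_pred <- predict(final, Xte_n) == "high"
  test_ev <- evaluate(test_pred, yte)

  report <- structure(list(
    cv = cv, test = test_ev, best = list(C = gs$C, gamma = gs$gamma),
    ranks = ranks, rank_table = agg, curve = curve$curve, best_k = best_k,
    selected = sel, pca = pca, reduced_dim = ncol(Xtr),
    test_subjects = sp$test_subjects, config = config
  ), class = "model_report")
  if (!is.null(out_dir)) persist_report(report, Xtr, Xte, sp, out_dir)
  report
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialized
# configuration, so every output file can declare exactly which
# parameter set produced it
config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, paste, "", collapse = ","),
               sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

persist_report <- function(report, Xtr, Xte, sp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(report$config)
  wr <- function(df, name) {
    write_feature_table(as.data.frame(df), file.path(out_dir, name))
    name
  }
  files <- c(
    wr(cbind(subject = sp$train$subject, as.data.frame(Xtr)),
       "reduced_train.csv"),
    wr(cbind(subject = sp$test$subject, as.data.frame(Xte)),
       "reduced_test.csv"),
    wr(report$cv$predictions, "cv_predictions.csv"),
    wr(report$cv$confusion, "cv_confusion.csv"),
    wr(report$test$confusion, "test_confusion.csv")
  )
  if (!is.null(report$rank_table)) {
    files <- c(files, wr(report$rank_table, "feature_ranks.csv"),
               wr(report$curve, "accuracy_curve.csv"))
  }
  write_run_config(report$config, file.path(out_dir, "run_config.txt"))
  log <- c(
    sprintf("seed: %d", report$config$seed),
    sprintf("config_hash: %s", hash),
    sprintf("target: %s", report$config$target),
    sprintf("best_C: %g  best_gamma: %g", report$best$C, report$best$gamma),
    sprintf("cv_accuracy: %.4f  test_accuracy: %.4f",
            report$cv$accuracy, report$test$accuracy),
    paste("files:", paste(files, collapse = " "))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> target=%s reduced dim=%d best C=%.3g gamma=%.3g\n",
              x$config$target, x$reduced_dim, x$best$C, x$best$gamma))
  cat(sprintf("  LOSO cv accuracy: %.2f%% (F = %.2f), top-%d features\n",
              x$cv$accuracy, x$cv$f_score, x$best_k))
  cat(sprintf("  test accuracy:    %.2f%% (F = %.2f) on subjects %s\n",
              x$test$accuracy, x$test$f_score,
              paste(x$test_subjects, collapse = ", ")))
  invisible(x)
}

#' Screen subjects against reference picture norms
#'
#' Each subject's arousal and valence rating of each reference picture
#' is converted to a z-score against the published norm mean/SD; a
#' subject is excluded when any |z| exceeds the two-sided critical value
#' for central 99% coverage of the reference population
#' (`qnorm(0.995)`, approximately 2.58).
#'
#' @param ratings data frame: `subject`, `picture`, `arousal`, `valence`.
#' @param norms data frame: `picture`, `arousal_mean`, `arousal_sd`,
#'   `valence_mean`, `valence_sd`; defaults to the reference norm table
#'   shipped with the package.
#' @param coverage central coverage retained (default 0.99).
#' @return object of class `screening_report`: per-subject max |z| per
#'   dimension and the exclusion flag; attribute `z_crit`.
#' @export
screen_subjects <- function(ratings, norms = reference_norms(),
                            coverage = 0.99) {
  if (any(norms$arousal_sd <= 0) || any(norms$valence_sd <= 0)) {
    reject("norm SDs must be positive", "affectpipe_bad_input")
  }
  z_crit <- stats::qnorm(1 - (1 - coverage) / 2)
  m <- merge(ratings, norms, by = "picture")
  if (nrow(m) == 0) reject("no pictures match the norms", "affectpipe_bad_input")
  m$z_arousal <- (m$arousal - m$arousal_mean) / m$arousal_sd
  m$z_valence <- (m$valence - m$valence_mean) / m$valence_sd
  agg <- do.call(rbind, lapply(split(m, m$subject), function(d) {
    data.frame(subject = d$subject[1],
               max_abs_z_arousal = max(abs(d$z_arousal)),
               max_abs_z_valence = max(abs(d$z_valence)))
  }))
  agg$excluded <- agg$max_abs_z_arousal > z_crit |
    agg$max_abs_z_valence > z_crit
  rownames(agg) <- NULL
  structure(agg, z_crit = z_crit,
            class = c("screening_report", "data.frame"))
}

#' Reference picture norms shipped with the package
#'
#' Published arousal/valence means and SDs of the eight standard
#' affective pictures used for subject screening.
#' @export
reference_norms <- function() {
  read.csv(system.file("extdata", "picture_norms.csv",
                       package = "affectpipe"))
}
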