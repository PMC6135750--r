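# The SVM half of the learning chain: leave-one-subject-out
# cross-validation with fold-internal normalization, sigmoid C-SVM grid
# search, recursive feature elimination with correlation bias reduction,
# rank aggregation, and evaluation.

label_factor <- function(y) factor(ifelse(y, "high", "low"),
                                   levels = c("high", "low"))

#' Default logarithmic parameter grid
#'
#' 15 values logarithmically spaced between 0.1 and 1000, used for both
#' the cost and gamma of the sigmoid C-SVM.
#' @export
svm_param_grid <- function(n = 15L, lo = 0.1, hi = 1000) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

fit_svm <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = label_factor(y), type = "C-classification",
             kernel = "sigmoid", cost = C, gamma = gamma, scale = FALSE)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the held-out subject's rows are predicted by a
#' sigmoid C-SVM trained on all remaining subjects, with median/MAD
#' normalization fitted on the training side of the fold only and applied
#' to both sides.
#'
#' @param X numeric feature matrix (rows = stimuli).
#' @param y logical labels (TRUE = high/positive).
#' @param subject subject id per row.
#' @param C,gamma SVM parameters.
#' @param features optional column subset (indices or names) to use.
#' @return list: `predictions` (data frame subject/truth/predicted),
#'   `accuracy` (%), `confusion` (row-percent matrix), `f_score`,
#'   `n_folds`.
#' @export
loso_cv <- function(X, y, subject, C = 1, gamma = NULL, features = NULL) {
  X <- as.matrix(X)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  gamma <- gamma %||% (1 / ncol(X))
  subs <- unique(subject)
  if (length(subs) < 3) reject("need >= 3 subjects", "affectpipe_bad_input")
  preds <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    hold <- subject == subs[i]
    if (!any(hold)) next
    Xtr <- normalize_median_mad(X[!hold, , drop = FALSE])
    Xte <- normalize_median_mad(X[!hold, , drop = FALSE],
                                X[hold, , drop = FALSE])
    model <- fit_svm(Xtr, y[!hold], C, gamma)
    p <- predict(model, Xte)
    preds[[i]] <- data.frame(subject = subs[i], truth = y[hold],
                             predicted = p == "high")
  }
  predictions <- do.call(rbind, preds)
  ev <- evaluate(predictions$predicted, predictions$truth)
  c(list(predictions = predictions, n_folds = length(subs)), ev)
}

#' Grid search for the sigmoid C-SVM parameters
#'
#' Evaluates LOSO accuracy over the (cost, gamma) grid; ties are broken
#' toward the smaller cost, then the smaller gamma, so the search is
#' fully deterministic.
#'
#' @inheritParams loso_cv
#' @param cost_grid,gamma_grid candidate values (default: 15 values
#'   log-spaced in 0.1..1000).
#' @return list: `C`, `gamma`, `accuracy` (best LOSO accuracy, %),
#'   `grid` (data frame of all combinations).
#' @export
grid_search_svm <- function(X, y, subject,
                            cost_grid = svm_param_grid(),
                            gamma_grid = svm_param_grid()) {
  if (length(cost_grid) == 0 || length(gamma_grid) == 0) {
    reject("parameter grids must be non-empty", "affectpipe_bad_input")
  }
  if (length(unique(y)) < 2) {
    reject("training data contain a single class", "affectpipe_bad_input")
  }
  grid <- expand.grid(C = sort(cost_grid), gamma = sort(gamma_grid))
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$accuracy[i] <- loso_cv(X, y, subject,
                                C = grid$C[i], gamma = grid$gamma[i])$accuracy
  }
  best <- grid[order(-grid$accuracy, grid$C, grid$gamma)[1], ]
  list(C = best$C, gamma = best$gamma, accuracy = best$accuracy, grid = grid)
}

# sigmoid kernel matrix as used by libsvm (coef0 = 0)
sigmoid_kernel <- function(A, B, gamma) tanh(gamma * tcrossprod(A, B))

# ||w||^2 in feature space from a fitted e1071 svm: alpha' Q alpha
svm_w2 <- function(model, SV, gamma) {
  co <- as.numeric(model$coefs)            # y_i * alpha_i at the SVs
  as.numeric(t(co) %*% sigmoid_kernel(SV, SV, gamma) %*% co)
}

#' SVM recursive feature elimination with correlation bias reduction
#'
#' At each step a sigmoid SVM is fitted on the surviving features and
#' every feature is scored by the margin criterion
#' `|W^2 - W^2(without j)|` recomputed through the kernel. Highly
#' correlated features (|Pearson r| > `cor_threshold`, grouped by graph
#' components) share information, which dilutes their individual scores;
#' the correlation-bias-reduction step replaces each member's score by
#' the group mean so a correlated group rises or falls as one. The
#' lowest-scoring feature is eliminated and the procedure repeats,
#' yielding a full elimination-order ranking (rank 1 = eliminated last).
#'
#' @param X numeric matrix (normalized training rows of one fold).
#' @param y logical labels.
#' @param C,gamma SVM parameters.
#' @param cor_threshold |r| above which features form a correlated group
#'   (default 0.85).
#' @return integer ranking vector named by feature (a permutation of
#'   1..ncol(X)).
#' @export
svm_rfe_cbr <- function(X, y, C = 1, gamma = NULL, cor_threshold = 0.85) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) reject("need >= 2 features", "affectpipe_bad_input")
  gamma <- gamma %||% (1 / p)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  surviving <- seq_len(p)
  rank_out <- integer(p)
  names(rank_out) <- colnames(X)
  next_rank <- p
  while (length(surviving) > 1) {
    Xs <- X[, surviving, drop = FALSE]
    model <- try_fit_svm(Xs, y, C, gamma)
    SV <- as.matrix(model$SV)
    w2_full <- svm_w2(model, SV, gamma)
    crit <- vapply(seq_along(surviving), function(j) {
      abs(w2_full - svm_w2(model, SV[, -j, drop = FALSE], gamma))
    }, numeric(1))
    crit <- cbr_adjust(Xs, crit, cor_threshold)
    drop_j <- which.min(crit)
    rank_out[surviving[drop_j]] <- next_rank
    next_rank <- next_rank - 1L
    surviving <- surviving[-drop_j]
  }
  rank_out[surviving] <- 1L
  rank_out
}

# replace each correlated-group member's criterion by the group mean
cbr_adjust <- function(X, crit, cor_threshold) {
  p <- ncol(X)
  if (p < 2) return(crit)
  cm <- suppressWarnings(abs(stats::cor(X)))
  cm[!is.finite(cm)] <- 0
  adj <- cm > cor_threshold
  # connected components of the correlation graph, by label propagation
  comp <- seq_len(p)
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) {
      nb <- which(adj[i, ])
      m <- min(comp[c(i, nb)])
      if (any(comp[c(i, nb)] != m)) {
        comp[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (g in unique(comp)) {
    idx <- comp == g
    if (sum(idx) > 1) crit[idx] <- mean(crit[idx])
  }
  crit
}

# RFE occasionally meets degenerate folds; retry with more regularization
try_fit_svm <- function(X, y, C, gamma, tries = 3L) {
  for (i in seq_len(tries)) {
    m <- tryCatch(fit_svm(X, y, C, gamma), error = function(e) NULL)
    if (!is.null(m) && length(m$coefs)) return(m)
    C <- C / 10
    warning("SVM fit failed; retrying with cost ", C)
  }
  reject("SVM did not converge during RFE", "affectpipe_bad_input")
}

#' Aggregate per-fold feature rankings by median rank
#'
#' @param rank_matrix folds x features matrix of ranks (or list of
#'   named rank vectors).
#' @return data frame ordered by final rank: `feature`, `median_rank`,
#'   `mean_rank`, `final_rank`.
#' @export
aggregate_ranks <- function(rank_matrix) {
  if (is.list(rank_matrix)) rank_matrix <- do.call(rbind, rank_matrix)
  med <- apply(rank_matrix, 2L, stats::median)
  mn <- colMeans(rank_matrix)
  ord <- order(med, mn, colnames(rank_matrix))
  out <- data.frame(feature = colnames(rank_matrix)[ord],
                    median_rank = med[ord], mean_rank = mn[ord],
                    final_rank = seq_along(ord), row.names = NULL)
  out
}

#' LOSO accuracy as a function of the number of top-ranked features
#'
#' @inheritParams loso_cv
#' @param ranking feature ordering (names or indices, best first), e.g.
#'   `aggregate_ranks(...)$feature`.
#' @return list: `curve` (data frame k/accuracy), `best_k` (smallest k
#'   attaining the maximum).
#' @export
accuracy_vs_rank_curve <- function(X, y, subject, ranking,
                                   C = 1, gamma = NULL) {
  X <- as.matrix(X)
  accs <- vapply(seq_along(ranking), function(k) {
    loso_cv(X, y, subject, C = C, gamma = gamma,
            features = ranking[seq_len(k)])$accuracy
  }, numeric(1))
  curve <- data.frame(k = seq_along(ranking), accuracy = accs)
  list(curve = curve, best_k = curve$k[which.max(curve$accuracy)])
}

#' Evaluate binary predictions
#'
#' @param predicted,truth logical vectors (TRUE = high/positive).
#' @return list: `confusion` (2 x 2, rows = true class, expressed as
#'   percentages summing to 100 per row), `accuracy` (%), `f_score`
#'   (harmonic mean of precision and recall for the positive class).
#' @export
evaluate <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    reject("predictions and labels must be non-empty and equal length",
           "affectpipe_bad_input")
  }
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  fp <- sum(predicted & !truth); tn <- sum(!predicted & !truth)
  conf <- matrix(0, 2, 2, dimnames = list(true = c("high", "low"),
                                          predicted = c("high", "low")))
  if (tp + fn > 0) conf[1, ] <- 100 * c(tp, fn) / (tp + fn)
  if (fp + tn > 0) conf[2, ] <- 100 * c(fp, tn) / (fp + tn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(confusion = conf, accuracy = 100 * (tp + tn) / length(truth),
       f_score = f, precision = precision, recall = recall)
}
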