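# Label handling, subject-wise splitting, block-wise PCA and robust
# normalization -- the deterministic half of the learning chain.

#' Bipolarize self-assessment scores
#'
#' Scores on the -4..+4 scale become binary labels: positive/high iff
#' the score is strictly greater than 0 (0 is low/negative).
#'
#' @param scores integer scores in -4..+4.
#' @return logical vector.
#' @export
bipolarize <- function(scores) {
  if (any(scores < -4 | scores > 4, na.rm = TRUE) || anyNA(scores)) {
    reject("scores must lie in -4..+4", "affectpipe_bad_input")
  }
  scores > 0
}

#' Split a feature table into train and test sets by subject
#'
#' The split is at the subject level (no subject contributes rows to both
#' sides); the test size is the subject count times `test_fraction`,
#' truncated to whole subjects (at least 1), so 38 subjects at 15% give a
#' 5-subject test set.
#'
#' @param features data frame with a `subject` column.
#' @param test_fraction fraction of subjects held out (default 0.15).
#' @param seed integer seed making the split reproducible.
#' @return list with `train` and `test` data frames and the chosen
#'   `test_subjects`.
#' @export
split_train_test <- function(features, test_fraction = 0.15, seed = 1L) {
  subjects <- unique(features$subject)
  if (length(subjects) < 7) {
    reject("need >= 7 subjects to split", "affectpipe_bad_input")
  }
  n_test <- max(1L, floor(test_fraction * length(subjects)))
  rng <- local_rng(seed)
  test_subjects <- rng(sort(subjects), n_test)
  list(
    train = features[!features$subject %in% test_subjects, , drop = FALSE],
    test = features[features$subject %in% test_subjects, , drop = FALSE],
    test_subjects = test_subjects
  )
}

# draw a sample without disturbing the caller's RNG stream
local_rng <- function(seed) {
  function(x, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(x, n)
  }
}

#' Fit block-wise PCA on training features
#'
#' One PCA per feature block (HRV, band power, MPC, identified by the
#' `hrv_` / `bp_` / `mpc_` column-name prefixes), fitted on the training
#' rows only, on standardized columns (the blocks mix ms^2, uV^2 and
#' dimensionless ratios). Constant or non-finite columns are dropped with
#' a warning before fitting. Per block, the smallest number of leading
#' components whose cumulative explained variance reaches
#' `variance_target` is retained.
#'
#' @param features data frame or matrix containing the feature columns.
#' @param variance_target cumulative explained-variance target
#'   (default 0.95).
#' @param blocks named list mapping block name to a regular expression
#'   matched against column names.
#' @return object of class `block_pca` with per-block rotation, centers,
#'   scales, retained counts.
#' @export
fit_block_pca <- function(features, variance_target = 0.95,
                          blocks = c(hrv = "^hrv_", bp = "^bp_",
                                     mpc = "^mpc_")) {
  X <- as.matrix(features[, grepl(paste(blocks, collapse = "|"),
                                  colnames(features)), drop = FALSE])
  if (nrow(X) < 2) reject("need >= 2 training rows", "affectpipe_bad_input")
  fits <- list()
  for (b in names(blocks)) {
    cols <- grep(blocks[[b]], colnames(X), value = TRUE)
    Xb <- X[, cols, drop = FALSE]
    ok <- apply(Xb, 2L, function(v) all(is.finite(v)) && stats::sd(v) > 0)
    if (any(!ok)) {
      warning(sprintf("block %s: dropping %d constant/non-finite columns",
                      b, sum(!ok)))
    }
    Xb <- Xb[, ok, drop = FALSE]
    pc <- stats::prcomp(Xb, center = TRUE, scale. = TRUE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- which(cum >= variance_target)[1]
    fits[[b]] <- list(cols = colnames(Xb), center = pc$center,
                      scale = pc$scale,
                      rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                      ncomp = ncomp, cum_var = cum[ncomp])
  }
  structure(list(blocks = fits, variance_target = variance_target),
            class = "block_pca")
}

#' Apply a fitted block PCA to new rows
#'
#' @param object a `block_pca`.
#' @param newdata data frame or matrix with the original feature columns.
#' @param ... unused.
#' @return numeric matrix of scores; columns named `<block>_pc<i>`.
#' @export
predict.block_pca <- function(object, newdata, ...) {
  out <- NULL
  for (b in names(object$blocks)) {
    f <- object$blocks[[b]]
    Xb <- as.matrix(newdata[, f$cols, drop = FALSE])
    Z <- scale(Xb, center = f$center, scale = f$scale) %*% f$rotation
    colnames(Z) <- paste0(b, "_pc", seq_len(ncol(Z)))
    out <- if (is.null(out)) Z else cbind(out, Z)
  }
  out
}

#' Median/MAD normalization fitted on training rows
#'
#' Each dimension is centered by the training median and scaled by the
#' training median absolute deviation (raw MAD, no consistency constant).
#' Dimensions with zero MAD fall back to a unit divisor and are recorded
#' in the `zero_mad` attribute.
#'
#' @param train numeric matrix of training rows.
#' @param apply_to numeric matrix to transform (defaults to `train`).
#' @return transformed `apply_to`; attributes `center`, `scale`,
#'   `zero_mad`.
#' @export
normalize_median_mad <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  med <- apply(train, 2L, stats::median)
  madv <- apply(train, 2L, function(v) stats::median(abs(v - stats::median(v))))
  zero <- madv == 0
  madv[zero] <- 1
  out <- sweep(sweep(apply_to, 2L, med), 2L, madv, "/")
  attr(out, "center") <- med
  attr(out, "scale") <- madv
  attr(out, "zero_mad") <- which(zero)
  out
}
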