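# Bipolarization, splitting, block PCA, normalization, LOSO, grid
# search, SVM-RFE with correlation bias reduction, evaluation.

test_that("bipolarization puts zero with the negative pole", {
  expect_false(bipolarize(0))
  expect_true(bipolarize(1))
  expect_false(bipolarize(-4))
  expect_identical(bipolarize(c(-4, 0, 1, 4)), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(bipolarize(5), class = "affectpipe_bad_input")
})

fake_table <- function(n_subjects, per = 4) {
  data.frame(subject = rep(sprintf("S%02d", 1:n_subjects), each = per),
             stimulus = rep(1:per, n_subjects))
}

test_that("train/test split is by subject, sized and reproducible", {
  tab <- fake_table(38)
  sp <- split_train_test(tab, 0.15, seed = 3)
  expect_length(sp$test_subjects, 5)
  expect_length(unique(sp$train$subject), 33)
  expect_length(intersect(sp$train$subject, sp$test$subject), 0)
  sp2 <- split_train_test(tab, 0.15, seed = 3)
  expect_identical(sp$test_subjects, sp2$test_subjects)
  expect_error(split_train_test(fake_table(5)),
               class = "affectpipe_bad_input")
})

test_that("the split does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(split_train_test(fake_table(10), seed = 7))
  expect_identical(runif(1), before)
})

test_that("block PCA: rank-1 block collapses, isotropic block does not", {
  set.seed(4)
  n <- 60
  base <- rnorm(n)
  dup <- data.frame(hrv_a = base, hrv_b = 2 * base + 5,
                    bp_1 = rnorm(n), mpc_1 = rnorm(n), mpc_2 = rnorm(n))
  fit <- fit_block_pca(dup)
  expect_equal(fit$blocks$hrv$ncomp, 1L)

  iso <- as.data.frame(matrix(rnorm(n * 10), n))
  names(iso) <- paste0("hrv_", 1:10)
  iso$bp_1 <- rnorm(n); iso$mpc_1 <- rnorm(n); iso$mpc_2 <- rnorm(n)
  fit2 <- fit_block_pca(iso)
  expect_gte(fit2$blocks$hrv$ncomp, 9L)
  for (b in fit2$blocks) expect_gte(b$cum_var, 0.95)
})

test_that("block PCA drops constant columns with a warning and projects held-out rows", {
  set.seed(5)
  tr <- data.frame(hrv_a = rnorm(30), hrv_b = rep(1, 30),
                   bp_1 = rnorm(30), mpc_1 = rnorm(30), mpc_2 = rnorm(30))
  expect_warning(fit <- fit_block_pca(tr), "constant")
  te <- tr[1:3, ]
  Z <- predict(fit, te)
  expect_equal(nrow(Z), 3)
  expect_identical(Z, predict(fit, te))     # deterministic transform
})

test_that("median/MAD normalization self-normalizes and is affine", {
  set.seed(6)
  X <- matrix(rnorm(200, 5, 3), 40)
  N <- normalize_median_mad(X)
  expect_true(all(abs(apply(N, 2, median)) < 1e-12))
  expect_true(all(abs(apply(N, 2, function(v)
    median(abs(v - median(v)))) - 1) < 1e-12))
  held <- matrix(attr(N, "center"), 1)
  expect_true(all(abs(normalize_median_mad(X, held)) < 1e-12))
  # permutation of rows leaves the fitted statistics unchanged
  N2 <- normalize_median_mad(X[sample(40), ])
  expect_equal(attr(N2, "center"), attr(N, "center"))
  expect_equal(attr(N2, "scale"), attr(N, "scale"))
  Xz <- cbind(X, 7)                         # zero-MAD dimension
  Nz <- normalize_median_mad(Xz)
  expect_identical(attr(Nz, "zero_mad"), 6L)
  expect_true(all(Nz[, 6] == 0))
})

sep_data <- function(n_subjects = 8, per = 6, gap = 3, seed = 1) {
  set.seed(seed)
  subject <- rep(sprintf("S%02d", 1:n_subjects), each = per)
  y <- rep(c(TRUE, FALSE), length.out = n_subjects * per)
  X <- matrix(rnorm(n_subjects * per * 4), ncol = 4)
  X[y, 1] <- X[y, 1] + gap
  colnames(X) <- paste0("f", 1:4)
  list(X = X, y = y, subject = subject)
}

test_that("LOSO produces one fold per subject and predicts every row", {
  d <- sep_data()
  cv <- loso_cv(d$X, d$y, d$subject, C = 1, gamma = 0.05)
  expect_equal(cv$n_folds, 8)
  expect_equal(nrow(cv$predictions), length(d$y))
  expect_true(all(abs(rowSums(cv$confusion) - 100) < 0.01))
  expect_gt(cv$accuracy, 80)               # separable by construction
  expect_error(loso_cv(d$X[1:12, ], d$y[1:12], d$subject[1:12]),
               class = "affectpipe_bad_input")
})

test_that("grid search uses the documented default grid and is deterministic", {
  g <- svm_param_grid()
  expect_length(g, 15)
  expect_equal(g[1], 0.1)
  expect_equal(g[15], 1000)
  d <- sep_data(n_subjects = 6)
  small <- svm_param_grid(4)
  gs1 <- grid_search_svm(d$X, d$y, d$subject, small, small)
  gs2 <- grid_search_svm(d$X, d$y, d$subject, small, small)
  expect_identical(gs1[c("C", "gamma", "accuracy")],
                   gs2[c("C", "gamma", "accuracy")])
  corners <- gs1$grid$accuracy[gs1$grid$C %in% range(small) &
                                 gs1$grid$gamma %in% range(small)]
  expect_gte(gs1$accuracy, max(corners))
  expect_error(grid_search_svm(d$X, rep(TRUE, length(d$y)), d$subject),
               class = "affectpipe_bad_input")
})

test_that("RFE median ranks put planted informative features above noise", {
  ranks <- t(sapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- rep(c(TRUE, FALSE), each = n / 2)
    X <- matrix(rnorm(n * 25), n)
    X[y, 1:5] <- X[y, 1:5] + 2
    colnames(X) <- paste0("f", 1:25)
    svm_rfe_cbr(normalize_median_mad(X), y, C = 1, gamma = 1 / 25)
  }))
  med <- apply(ranks, 2L, median)
  expect_lt(max(med[1:5]), min(med[6:25]))
})

test_that("RFE output is a permutation and CBR keeps duplicates together", {
  set.seed(11)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 10), n)
  X[y, 1] <- X[y, 1] + 3
  X <- cbind(X, X[, 1])                     # perfect duplicate of the signal
  colnames(X) <- paste0("f", 1:11)
  r <- svm_rfe_cbr(normalize_median_mad(X), y, C = 1, gamma = 1 / 11)
  expect_setequal(r, 1:11)
  # both copies of the informative feature must sit in the top group
  expect_lte(max(r[c(1, 11)]), 4)
  expect_error(svm_rfe_cbr(X[, 1, drop = FALSE], y),
               class = "affectpipe_bad_input")
})

test_that("median-rank aggregation is idempotent and well-defined", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  colnames(m) <- c("a", "b", "c")
  agg <- aggregate_ranks(m)
  expect_identical(agg$feature, c("a", "b", "c"))
  expect_identical(agg$final_rank, 1:3)
  m2 <- rbind(c(1, 9), c(3, 9), c(5, 9))
  colnames(m2) <- c("x", "y")
  expect_equal(aggregate_ranks(m2)$median_rank[1], 3)
  expect_equal(nrow(aggregate_ranks(m2)), 2)
})

test_that("accuracy-vs-rank curve is complete and consistent", {
  d <- sep_data(n_subjects = 6)
  r <- svm_rfe_cbr(normalize_median_mad(d$X), d$y, C = 1, gamma = 0.25)
  ranking <- names(sort(r))
  cur <- accuracy_vs_rank_curve(d$X, d$y, d$subject, ranking,
                                C = 1, gamma = 0.25)
  expect_identical(cur$curve$k, 1:4)
  full <- loso_cv(d$X, d$y, d$subject, C = 1, gamma = 0.25)
  expect_equal(cur$curve$accuracy[4], full$accuracy)
  expect_gte(cur$curve$accuracy[cur$best_k], cur$curve$accuracy[1])
})

test_that("evaluation reproduces hand-computed contingency metrics", {
  ev <- evaluate(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$f_score, 1)
  expect_identical(unname(diag(ev$confusion)), c(100, 100))
  ev0 <- evaluate(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(ev0$accuracy, 0)
  # TP=3 FP=1 FN=1 TN=5
  pred <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  truth <- c(rep(TRUE, 3), TRUE, FALSE, rep(FALSE, 5))
  ev2 <- evaluate(pred, truth)
  expect_equal(ev2$precision, 0.75)
  expect_equal(ev2$recall, 0.75)
  expect_equal(ev2$f_score, 0.75)
  expect_error(evaluate(logical(0), logical(0)),
               class = "affectpipe_bad_input")
})

test_that("held-out labels cannot leak into fold-fitted transforms", {
  d <- sep_data(n_subjects = 6)
  hold <- d$subject == "S01"
  fitA <- normalize_median_mad(d$X[!hold, ])
  yB <- d$y
  yB[hold] <- !yB[hold]                     # permute held-out labels
  fitB <- normalize_median_mad(d$X[!hold, ])
  expect_identical(attr(fitA, "center"), attr(fitB, "center"))
  tab <- as.data.frame(d$X)
  names(tab) <- paste0("hrv_", 1:4)
  tab$bp_1 <- rnorm(nrow(tab)); tab$mpc_1 <- rnorm(nrow(tab))
  tab$mpc_2 <- rnorm(nrow(tab))
  pA <- fit_block_pca(tab[!hold, ])
  pB <- fit_block_pca(tab[!hold, ])
  expect_identical(predict(pA, tab[hold, ]), predict(pB, tab[hold, ]))
})
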