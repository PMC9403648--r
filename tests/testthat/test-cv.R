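test_that("accuracy metrics match hand computation and edge cases", {
  actual <- c(1, 2, 3, 4)
  pred <- c(1.5, 1.5, 3.5, 3.5)
  m <- accuracy_metrics(actual, pred)
  expect_equal(m$r, 4 / sqrt(20), tolerance = 1e-12)
  expect_equal(m$r2, 0.8)
  expect_equal(m$rmse, 0.5)
  id <- accuracy_metrics(actual, actual)
  expect_equal(unlist(id), c(r = 1, r2 = 1, rmse = 0))
  # predicting the mean gives R2 = 0
  expect_equal(accuracy_metrics(actual, rep(mean(actual), 4))$r2, 0)
  expect_error(accuracy_metrics(rep(1, 4), pred), "degenerate target")
  expect_error(accuracy_metrics(1:4, 1:3), "length mismatch")
})

test_that("repeated CV emits reps x folds weight maps and is reproducible", {
  set.seed(10)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- X %*% rnorm(8) + rnorm(60)
  cv <- repeated_cv(X, y, folds = 4, reps = 3, n_components = 2, seed = 1)
  expect_equal(ncol(cv$fold_weight_maps), 12L)
  expect_equal(nrow(cv$fold_weight_maps), 8L)
  expect_equal(nrow(cv$per_rep), 3L)
  cv2 <- repeated_cv(X, y, folds = 4, reps = 3, n_components = 2, seed = 1)
  expect_identical(cv, cv2)
  expect_error(repeated_cv(X[1:7, ], y[1:7], folds = 4), "insufficient data")
})

test_that("CV accuracy is near zero for a target independent of the features", {
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- rnorm(200)
  cv <- repeated_cv(X, y, folds = 10, reps = 5, n_components = 1, seed = 2,
                    keep_fold_maps = FALSE)
  expect_lt(abs(cv$summary$r_mean), 0.1)
})

test_that("CV accuracy approaches 1 as the generator noise vanishes", {
  a <- atlas8(3)
  sp <- synthetic_spec(a, n_subjects = 100, noise_sd = 0.02, seed = 12)
  co <- simulate_cohort(sp)
  cv <- repeated_cv(co$connectomes, co$cohort$age, folds = 5, reps = 2,
                    n_components = 2, seed = 1, keep_fold_maps = FALSE)
  expect_gt(cv$summary$r_mean, 0.97)
  expect_lt(cv$summary$rmse_mean, 0.25 * sd(co$cohort$age))
})

test_that("test-fold targets never leak into training-fold coefficients", {
  set.seed(13)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X %*% rnorm(6) + rnorm(n)
  # reconstruct the partition the engine draws under this seed
  set.seed(99)
  fold_id <- sample(rep_len(1:5, n))
  y2 <- y
  y2[fold_id == 1] <- sample(y2[fold_id == 1])
  cv_a <- repeated_cv(X, y, folds = 5, reps = 1, n_components = 2, seed = 99)
  cv_b <- repeated_cv(X, y2, folds = 5, reps = 1, n_components = 2, seed = 99)
  # fold 1's model is trained without fold-1 subjects: identical coefficients
  expect_identical(cv_a$fold_weight_maps[, 1], cv_b$fold_weight_maps[, 1])
  # other folds see the shuffled values in training and must differ
  expect_false(identical(cv_a$fold_weight_maps[, 2], cv_b$fold_weight_maps[, 2]))
})

test_that("permutation p-values use the add-one estimator", {
  expect_equal(perm_pvalue(1, rep(0, 5000)), 1 / 5001)
  expect_lte(perm_pvalue(1, rep(0, 5000)), 2.0e-4)
  expect_equal(perm_pvalue(-1, rep(0, 999)), 1.0)
  nulls <- c(rep(1, 49), rep(-1, 950))
  expect_equal(perm_pvalue(0.5, nulls), 0.05)
  expect_error(perm_pvalue(1, numeric(0)), "empty null")
})

test_that("permutation test flags real signal and validates n_perm", {
  set.seed(14)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- X %*% rnorm(5) + 0.3 * rnorm(50)
  pt <- permutation_test(X, y, folds = 5, reps = 2, n_components = 2,
                         n_perm = 99, seed = 1)
  expect_lt(pt$p_value, 0.05)
  expect_length(pt$null_values, 99)
  expect_equal(pt$reps_per_perm, 1L)
  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")
})

test_that("partial accuracy equals the two-stage residualization oracle", {
  set.seed(15)
  n <- 40
  actual <- rnorm(n)
  predicted <- 0.6 * actual + rnorm(n)
  z <- cbind(rnorm(n), rnorm(n))
  pa <- partial_accuracy(actual, predicted, z)
  res_a <- resid(lm(actual ~ z))
  res_p <- resid(lm(predicted ~ z))
  expect_equal(pa$r, cor(res_a, res_p), tolerance = 1e-12)
  # covariate orthogonal to both vectors leaves the correlation unchanged
  on <- orthonormal_pair(24, seed = 21)
  a2 <- on$u
  p2 <- 0.5 * on$u + sqrt(0.75) * on$w
  ortho <- rnorm(24)
  ortho <- resid(lm(ortho ~ a2 + p2))
  expect_equal(partial_accuracy(a2, p2, ortho)$r, cor(a2, p2),
               tolerance = 1e-10)
  # prediction fully explained by the covariate: partial r ~ 0
  cvr <- rnorm(n)
  pa0 <- partial_accuracy(actual, cvr, cvr)
  expect_lt(abs(pa0$r), 1e-6)
  expect_error(partial_accuracy(actual, predicted, cbind(z[, 1], z[, 1])),
               "collinearity")
})

test_that("covariate screening retains the right edges", {
  set.seed(16)
  n <- 300
  covar <- rnorm(n)
  X <- cbind(covar + rnorm(n, sd = 0.01),       # pure covariate edge
             rnorm(n),                          # noise edge
             0.5 * rnorm(n) + 0.5 * scale(resid(lm(rnorm(n) ~ covar))))
  y_extra <- rnorm(n)
  y <- 0.8 * X[, 3] + 0.3 * covar + 0.3 * y_extra
  mask <- screen_out_covariate_edges(X, y, covar, alpha = 0.05)
  expect_false(mask[1])
  expect_true(mask[3])
  # vacuous threshold keeps everything
  expect_true(all(screen_out_covariate_edges(X, y, covar, alpha = 1)))
  # nothing survives an impossible threshold
  expect_error(screen_out_covariate_edges(X[, 1:2], rnorm(n), covar,
                                          alpha = 1e-12), "no-features")
})

test_that("CPM selects sign-split edges and predicts linearly", {
  set.seed(17)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- 2 * X[, 2] + rnorm(n, sd = 0.3)
  tr <- 1:100
  te <- 101:120
  fit <- cpm_fit_predict(X[tr, ], y[tr], X[te, ], p_threshold = 0.01)
  expect_equal(fit$pos_edges, 2L)
  expect_length(fit$neg_edges, 0)
  expect_gt(cor(fit$predictions, y[te]), 0.8)
  # vacuous threshold on a 2-edge toy: both selected, partitioned by sign
  X2 <- cbind(y + rnorm(n, sd = 0.1), -y + rnorm(n, sd = 0.1))
  fit2 <- cpm_fit_predict(X2[tr, ], y[tr], X2[te, ], p_threshold = 1)
  expect_equal(fit2$pos_edges, 1L)
  expect_equal(fit2$neg_edges, 2L)
  expect_error(cpm_fit_predict(matrix(rnorm(200), 100, 2), rnorm(100),
                               matrix(rnorm(20), 10, 2), p_threshold = 1e-12),
               "no-features")
})

test_that("CPM and PLSR network-level weight patterns agree on synthetic data", {
  fx <- fixture_cohort()
  y <- fx$cohort$age
  n <- nrow(fx$X)
  set.seed(18)
  tr <- sample(n, 250)
  te <- setdiff(seq_len(n), tr)
  cpm <- cpm_fit_predict(fx$X[tr, ], y[tr], fx$X[te, ], p_threshold = 0.01)
  cpm_map <- numeric(ncol(fx$X))
  cpm_map[cpm$pos_edges] <- 1
  cpm_map[cpm$neg_edges] <- -1
  pls <- fit_plsr(fx$X[tr, ], y[tr], n_components = 2)
  ns_cpm <- network_summary(cpm_map, fx$atlas)$map
  ns_pls <- network_summary(pls$coefficients, fx$atlas)$map
  expect_gt(cor(ns_cpm$values, ns_pls$values), 0)
})

test_that("motion filtering uses a strict cutoff and preserves order", {
  coh <- data.frame(subject_id = 1:3, mean_fd = c(0.1, 0.15, 0.3))
  expect_equal(nrow(filter_by_motion(coh, Inf)), 3)
  kept <- filter_by_motion(coh, 0.15)
  expect_equal(kept$subject_id, 1L)
  fx <- fixture_cohort()
  med <- median(fx$cohort$mean_fd)
  n_kept <- nrow(filter_by_motion(fx$cohort, med))
  expect_true(n_kept %in% c(floor(300 / 2), ceiling(300 / 2)))
  expect_warning(filter_by_motion(coh, 0.01), "empty cohort")
  expect_error(filter_by_motion(data.frame(x = 1), 1), "mean_fd")
})

test_that("screening inside CV keeps masked edges at zero weight", {
  set.seed(19)
  n <- 80
  covar <- rnorm(n)
  X <- cbind(covar + rnorm(n, sd = 0.05), matrix(rnorm(n * 5), n, 5))
  y <- 1.5 * X[, 3] + 0.5 * covar + rnorm(n, sd = 0.5)
  cv <- repeated_cv(X, y, folds = 4, reps = 2, n_components = 2, seed = 1,
                    screen_covariates = covar)
  # the covariate-duplicate edge should essentially never be retained
  expect_lt(mean(cv$fold_weight_maps[1, ] != 0), 0.5)
  expect_gt(mean(cv$fold_weight_maps[3, ] != 0), 0.5)
})
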