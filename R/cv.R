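# Repeated k-fold cross-validation, accuracy metrics, permutation
# significance, covariate control, feature screening, the CPM alternative
# model family, and motion filtering.

#' Prediction accuracy metrics
#'
#' @param actual Observed target values (length >= 3, not constant).
#' @param predicted Predicted values, same length.
#' @return List with `r` (Pearson correlation), `r2` (cross-validated
#'   coefficient of determination, `1 - SSE/SST`; may be negative) and
#'   `rmse`.
#' @export
accuracy_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("invalid input: length mismatch")
  if (length(actual) < 3) stop("invalid input: need at least 3 observations")
  if (stats::sd(actual) == 0) stop("degenerate target: `actual` is constant")
  err <- actual - predicted
  r <- if (stats::sd(predicted) == 0) NA_real_ else stats::cor(actual, predicted)
  list(r = r,
       r2 = 1 - sum(err^2) / sum((actual - mean(actual))^2),
       rmse = sqrt(mean(err^2)))
}

# One pass of k-fold CV with the current RNG stream. Returns predictions
# and (optionally) the per-fold coefficient vectors. Screening, when
# requested, is computed on the training folds only.
.cv_once <- function(X, y, folds, n_components, keep_maps = FALSE,
                     screen_covariates = NULL, screen_alpha = 0.05) {
  n <- nrow(X)
  fold_id <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  maps <- if (keep_maps) matrix(0, ncol(X), folds) else NULL
  for (f in seq_len(folds)) {
    te <- fold_id == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    keep <- TRUE
    if (!is.null(screen_covariates)) {
      cv_tr <- as.matrix(screen_covariates)[!te, , drop = FALSE]
      keep <- screen_out_covariate_edges(Xtr, ytr, cv_tr, alpha = screen_alpha)
      Xtr <- Xtr[, keep, drop = FALSE]
    }
    nc <- if (is.null(n_components)) NULL else min(n_components, sum(!te) - 1L, ncol(Xtr))
    fit <- if (is.null(nc)) {
      fit_plsr(Xtr, ytr)
    } else {
      path <- .simpls_path(Xtr, ytr, nc)
      b <- path$B[, nc]
      list(coefficients = b, intercept = path$y_center - sum(path$x_center * b))
    }
    pred[te] <- X[te, keep, drop = FALSE] %*% fit$coefficients + fit$intercept
    if (keep_maps) {
      w <- numeric(ncol(X))
      w[keep] <- fit$coefficients
      maps[, f] <- w
    }
  }
  list(pred = pred, maps = maps)
}

#' Repeated k-fold cross-validated prediction
#'
#' Runs PLSR prediction inside repeated k-fold cross-validation with a
#' fresh random partition per repetition. Models are fit on training folds
#' only (including centring statistics and, when `screen_covariates` is
#' given, the partial-correlation feature screen) and applied to the held
#' out fold without modification.
#'
#' @param X Numeric matrix, subjects x edges.
#' @param y Target vector.
#' @param folds Number of folds (default 10). Requires
#'   `nrow(X) >= 2 * folds`.
#' @param reps Number of repetitions (default 200).
#' @param n_components Fixed component count, or `NULL` for the per-fold
#'   inner-CV rule (slower).
#' @param seed Integer seed governing all partitions.
#' @param screen_covariates Optional covariate matrix/vector; when given,
#'   each training fold retains only edges whose partial correlation with
#'   the target given the covariates has `p < screen_alpha`, and the model
#'   is fit on the retained edges (coefficients of screened-out edges are
#'   zero in the emitted maps).
#' @param screen_alpha Screening threshold (default 0.05).
#' @param keep_fold_maps Keep the `edges x (reps * folds)` matrix of fold
#'   coefficient vectors (default `TRUE`).
#' @return Object of class `cv_result`: `per_rep` (data.frame with `r`,
#'   `r2`, `rmse` per repetition), `summary` (means and SDs over
#'   repetitions), `predicted` (per-subject mean prediction across
#'   repetitions), `fold_weight_maps`, plus the resolved settings.
#' @export
repeated_cv <- function(X, y, folds = 10L, reps = 200L, n_components = NULL,
                        seed = 1L, screen_covariates = NULL,
                        screen_alpha = 0.05, keep_fold_maps = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("invalid input: length(y) != nrow(X)")
  if (n < 2 * folds) {
    stop("insufficient data: need at least 2 x folds = ", 2 * folds, " subjects")
  }
  set.seed(seed)
  per_rep <- data.frame(rep = seq_len(reps), r = NA_real_, r2 = NA_real_,
                        rmse = NA_real_)
  pred_sum <- numeric(n)
  maps <- if (keep_fold_maps) matrix(0, ncol(X), reps * folds) else NULL
  for (rp in seq_len(reps)) {
    one <- .cv_once(X, y, folds, n_components, keep_maps = keep_fold_maps,
                    screen_covariates = screen_covariates,
                    screen_alpha = screen_alpha)
    m <- accuracy_metrics(y, one$pred)
    per_rep$r[rp] <- m$r
    per_rep$r2[rp] <- m$r2
    per_rep$rmse[rp] <- m$rmse
    pred_sum <- pred_sum + one$pred
    if (keep_fold_maps) maps[, ((rp - 1L) * folds + 1L):(rp * folds)] <- one$maps
  }
  structure(list(
    per_rep = per_rep,
    summary = list(r_mean = mean(per_rep$r), r_sd = stats::sd(per_rep$r),
                   r2_mean = mean(per_rep$r2), r2_sd = stats::sd(per_rep$r2),
                   rmse_mean = mean(per_rep$rmse), rmse_sd = stats::sd(per_rep$rmse)),
    predicted = pred_sum / reps,
    fold_weight_maps = maps,
    folds = as.integer(folds), reps = as.integer(reps),
    n_components = n_components, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Repeated %d-fold CV, %d repetitions\n  r    = %.3f +/- %.3f\n  R2   = %.3f +/- %.3f\n  RMSE = %.3f +/- %.3f\n",
    x$folds, x$reps, s$r_mean, s$r_sd, s$r2_mean, s$r2_sd, s$rmse_mean, s$rmse_sd))
  invisible(x)
}

#' Permutation p-value
#'
#' Uses the add-one estimator `(1 + #exceedances) / (1 + n_perm)`, which
#' never returns zero; with 5000 permutations and no exceedances the floor
#' is `1/5001` (just below 2.0e-4).
#'
#' @param observed Observed statistic.
#' @param null_values Vector of null statistics.
#' @param two_sided Compare `|null| >= |observed|` instead of
#'   `null >= observed`.
#' @return P-value in `(0, 1]`.
#' @export
perm_pvalue <- function(observed, null_values, two_sided = FALSE) {
  if (length(null_values) < 1) stop("invalid parameter: empty null")
  exceed <- if (two_sided) {
    sum(abs(null_values) >= abs(observed))
  } else {
    sum(null_values >= observed)
  }
  (1 + exceed) / (1 + length(null_values))
}

#' Permutation test of cross-validated prediction accuracy
#'
#' The observed statistic is the mean CV correlation over `reps`
#' repetitions. Each permutation shuffles the target independently and
#' reruns the full CV pipeline with `reps_per_perm` repetitions (default 1,
#' recorded in the output); the null statistic is its mean r.
#'
#' @param X,y,folds,n_components As in [repeated_cv()].
#' @param reps Repetitions for the observed statistic.
#' @param n_perm Number of permutations (default 5000).
#' @param reps_per_perm Repetitions per permutation (default 1).
#' @param seed Integer seed.
#' @return List with `observed`, `null_values`, `p_value`, and resolved
#'   settings.
#' @export
permutation_test <- function(X, y, folds = 10L, reps = 10L,
                             n_components = NULL, n_perm = 5000L,
                             reps_per_perm = 1L, seed = 1L) {
  if (n_perm < 1) stop("invalid parameter: n_perm must be >= 1")
  X <- as.matrix(X)
  obs_cv <- repeated_cv(X, y, folds = folds, reps = reps,
                        n_components = n_components, seed = seed,
                        keep_fold_maps = FALSE)
  observed <- obs_cv$summary$r_mean
  null_values <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- sample(y)
    rs <- numeric(reps_per_perm)
    for (rp in seq_len(reps_per_perm)) {
      rs[rp] <- stats::cor(yb, .cv_once(X, yb, folds, n_components)$pred)
    }
    null_values[b] <- mean(rs)
  }
  list(observed = observed, null_values = null_values,
       p_value = perm_pvalue(observed, null_values),
       n_perm = as.integer(n_perm), reps_per_perm = as.integer(reps_per_perm),
       folds = as.integer(folds), reps = as.integer(reps), seed = seed)
}

# Residuals after regressing each column of `m` on [1, covariates].
.residualize <- function(m, covariates) {
  d <- cbind(1, as.matrix(covariates))
  q <- qr(d)
  if (q$rank < ncol(d)) stop("collinearity error: covariate matrix is rank deficient")
  qr.resid(q, as.matrix(m))
}

#' Partial correlation between actual and predicted scores
#'
#' Pearson correlation between the residuals of both vectors after linear
#' regression on the covariates; the paper's device for checking that
#' accuracy survives controlling for head motion.
#'
#' @param actual,predicted Numeric vectors.
#' @param covariates Covariate vector or matrix (full rank with intercept).
#' @return List with `r`, `p` (two-sided, t-distribution with
#'   `n - 2 - k` df) and `df`.
#' @export
partial_accuracy <- function(actual, predicted, covariates) {
  n <- length(actual)
  if (length(predicted) != n) stop("invalid input: length mismatch")
  res <- .residualize(cbind(actual, predicted), covariates)
  # a vector fully explained by the covariates has no residual variation
  if (stats::sd(res[, 1L]) < 1e-12 || stats::sd(res[, 2L]) < 1e-12) {
    return(list(r = 0, p = 1, df = n - 2L - ncol(as.matrix(covariates))))
  }
  r <- stats::cor(res[, 1L], res[, 2L])
  k <- ncol(as.matrix(covariates))
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Screen out covariate-associated edges
#'
#' Retains edges whose partial correlation with the target, given the
#' covariates, is significant at `alpha`. Used inside cross-validation to
#' build cognition models from connections independent of the age effect;
#' must be computed on training folds only.
#'
#' @param X Training feature matrix.
#' @param y Training target.
#' @param covariates Covariate vector/matrix (e.g. age).
#' @param alpha Retention threshold on the two-sided p (default 0.05).
#' @return Logical mask over edges. Errors if no edge survives.
#' @export
screen_out_covariate_edges <- function(X, y, covariates, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  res <- .residualize(cbind(y, X), covariates)
  ry <- res[, 1L]
  rx <- res[, -1L, drop = FALSE]
  sy <- sqrt(sum(ry^2))
  sx <- sqrt(colSums(rx^2))
  r <- as.vector(crossprod(rx, ry)) / (sx * sy)
  r[!is.finite(r)] <- 0
  k <- ncol(as.matrix(covariates))
  df <- n - 2L - k
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df)
  mask <- p < alpha
  if (!any(mask)) {
    stop("no-features error: no edge passes the partial-correlation screen at alpha = ",
         alpha)
  }
  mask
}

#' Connectome-based predictive modelling (CPM) fit and predict
#'
#' The classical CPM recipe: edges correlated with the training target at
#' `p < p_threshold` are split by correlation sign; each subject's positive
#' and negative network strengths (sums over the selected edges) enter a
#' linear model fitted on the training set and applied to the test set.
#'
#' @param X_train,y_train Training features and target.
#' @param X_test Test features (disjoint subjects).
#' @param p_threshold Edge-selection threshold (default 0.01).
#' @return List with `predictions`, `pos_edges`, `neg_edges` (integer
#'   indices) and the fitted `coefficients`.
#' @export
cpm_fit_predict <- function(X_train, y_train, X_test, p_threshold = 0.01) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  n <- nrow(X_train)
  r <- as.vector(stats::cor(X_train, y_train))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  pos <- which(p < p_threshold & r > 0)
  neg <- which(p < p_threshold & r < 0)
  if (!length(pos) && !length(neg)) {
    stop("no-features error: no edge passes the CPM threshold p < ", p_threshold)
  }
  strength <- function(M) {
    out <- NULL
    if (length(pos)) out <- cbind(out, pos = rowSums(M[, pos, drop = FALSE]))
    if (length(neg)) out <- cbind(out, neg = rowSums(M[, neg, drop = FALSE]))
    out
  }
  str_tr <- strength(X_train)
  fit <- stats::lm.fit(cbind(1, str_tr), y_train)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  preds <- drop(cbind(1, strength(X_test)) %*% co)
  list(predictions = preds, pos_edges = pos, neg_edges = neg,
       coefficients = co)
}

#' Filter a cohort by mean framewise displacement
#'
#' Retains subjects with `mean_fd` strictly below `fd_max`, preserving
#' order; the paper's low-motion sensitivity subsets use cutoffs of 0.15
#' and 0.20 mm.
#'
#' @param cohort Data.frame with a `mean_fd` column.
#' @param fd_max Cutoff in mm (strict inequality).
#' @return The retained subset (warns if empty).
#' @export
filter_by_motion <- function(cohort, fd_max) {
  if (!"mean_fd" %in% names(cohort)) stop("invalid input: no `mean_fd` column")
  out <- cohort[cohort$mean_fd < fd_max, , drop = FALSE]
  if (nrow(out) == 0) warning("empty cohort: no subject has mean_fd < ", fd_max)
  out
}
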