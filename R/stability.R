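# Robustness battery: inter-correlation of fold-level weight maps,
# bootstrap weight maps, and network-restricted prediction runs.

#' Inter-correlation of fold-level weight maps
#'
#' Pearson correlation over distinct map pairs. With many maps (200 reps x
#' 10 folds gives ~2e6 pairs) a seeded random subset of `max_pairs` pairs
#' estimates the same mean and SD.
#'
#' @param fold_maps `edges x n_models` matrix or list of vectors (>= 2).
#' @param max_pairs Maximum number of distinct pairs evaluated (default
#'   10000).
#' @param seed Integer seed for pair sampling.
#' @return List with `mean`, `sd` and `n_pairs`.
#' @export
weight_intercorrelation <- function(fold_maps, max_pairs = 10000L, seed = 1L) {
  if (is.list(fold_maps) && !is.data.frame(fold_maps)) {
    fold_maps <- do.call(cbind, fold_maps)
  }
  fold_maps <- as.matrix(fold_maps)
  m <- ncol(fold_maps)
  if (m < 2) stop("insufficient input: need at least 2 maps")
  pairs <- edge_pairs(m)
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  rs <- vapply(seq_len(nrow(pairs)), function(k) {
    stats::cor(fold_maps[, pairs[k, 1L]], fold_maps[, pairs[k, 2L]])
  }, numeric(1))
  list(mean = mean(rs), sd = stats::sd(rs), n_pairs = nrow(pairs))
}

#' Bootstrap weight map
#'
#' Resamples subjects with replacement, refits the full-data PLSR model on
#' each resample, and averages the coefficient vectors. Degenerate
#' resamples (constant target) are redrawn and counted.
#'
#' @param X Subjects x edges matrix.
#' @param y Target vector.
#' @param n_boot Number of bootstrap samples (default 5000).
#' @param n_components Component count or `NULL` for the inner-CV rule
#'   (re-run per resample).
#' @param seed Integer seed.
#' @return List with `map` (connection-level `weight_map`, the bootstrap
#'   mean), `sd` (per-edge bootstrap SD) and `n_redrawn`.
#' @export
bootstrap_weights <- function(X, y, n_boot = 5000L, n_components = NULL,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("insufficient input: need at least 10 subjects")
  set.seed(seed)
  p <- ncol(X)
  acc <- numeric(p)
  acc2 <- numeric(p)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    w <- if (is.null(n_components)) {
      fit_plsr(Xb, yb)$coefficients
    } else {
      nc <- min(n_components, n - 1L, p)
      .simpls_path(Xb, yb, nc)$B[, nc]
    }
    acc <- acc + w
    acc2 <- acc2 + w^2
  }
  mean_w <- acc / n_boot
  var_w <- pmax(acc2 / n_boot - mean_w^2, 0) * n_boot / max(n_boot - 1L, 1L)
  list(map = weight_map(mean_w, "connection", n_models_averaged = n_boot),
       sd = sqrt(var_w), n_redrawn = n_redrawn)
}

#' Network-restricted prediction runs
#'
#' Reruns repeated cross-validation using only the edges of each network
#' pair in turn (36 runs with 8 networks), plus the whole-brain run, and
#' reports the Spearman correlation between a pair's edge count and its
#' accuracy, probing whether network size rather than identity drives
#' restricted-model accuracy.
#'
#' @param X Subjects x edges matrix (canonical edge order for `atlas`).
#' @param y Target vector.
#' @param atlas Atlas defining the network pairs.
#' @param folds,reps,n_components,seed CV settings, as [repeated_cv()].
#' @return List with `per_pair` (data.frame `net_a`, `net_b`, `n_edges`,
#'   `r_mean`, `r_sd`; pairs with fewer than 2 edges are skipped with a
#'   warning and reported as `NA`), `whole_brain` (its `r_mean`, `r_sd`)
#'   and `size_accuracy_spearman`.
#' @export
network_restricted_cv <- function(X, y, atlas, folds = 10L, reps = 10L,
                                  n_components = NULL, seed = 1L) {
  X <- as.matrix(X)
  ec <- edge_classes(atlas)
  if (ncol(X) != length(ec$edge_class)) {
    stop("shape error: X has ", ncol(X), " edges but atlas implies ",
         length(ec$edge_class))
  }
  np <- nrow(ec$pairs)
  out <- ec$pairs
  out$r_mean <- NA_real_
  out$r_sd <- NA_real_
  for (p in seq_len(np)) {
    cols <- which(ec$edge_class == p)
    if (length(cols) < 2) {
      warning("skipped network pair ", out$net_a[p], "-", out$net_b[p],
              ": fewer than 2 edges")
      next
    }
    cv <- repeated_cv(X[, cols, drop = FALSE], y, folds = folds, reps = reps,
                      n_components = if (is.null(n_components)) NULL else
                        min(n_components, length(cols)),
                      seed = seed + p, keep_fold_maps = FALSE)
    out$r_mean[p] <- cv$summary$r_mean
    out$r_sd[p] <- cv$summary$r_sd
  }
  wb <- repeated_cv(X, y, folds = folds, reps = reps,
                    n_components = n_components, seed = seed,
                    keep_fold_maps = FALSE)
  rho <- stats::cor(out$n_edges, out$r_mean, method = "spearman",
                    use = "complete.obs")
  list(per_pair = out,
       whole_brain = list(r_mean = wb$summary$r_mean, r_sd = wb$summary$r_sd),
       size_accuracy_spearman = rho)
}
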