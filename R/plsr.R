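# Partial least squares regression, SIMPLS algorithm (de Jong 1993), for a
# single response. Features and target are mean-centred with training
# statistics only; no variance scaling by default (connectome edges share
# units). For a single response SIMPLS coincides with PLS1, so coefficients
# are directly comparable with other PLS implementations.

# Core SIMPLS path: returns the p x A matrix whose column a holds the
# coefficient vector using components 1..a, plus centring statistics.
# X is n x p raw (uncentred), y length n. Lean on purpose: called inside
# tight cross-validation and permutation loops.
.simpls_path <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm, check.margin = FALSE)
  yc <- y - ym
  S <- crossprod(Xc, yc)              # p x 1
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    tt <- Xc %*% r
    nt <- sqrt(sum(tt^2))
    if (!is.finite(nt) || nt < 1e-12) break   # residual signal exhausted
    tt <- tt / nt
    r <- r / nt
    pv <- crossprod(Xc, tt)
    Q[a] <- sum(yc * tt)
    v <- pv
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    used <- a
  }
  # cumulative coefficient paths; columns past `used` repeat the last fit
  B <- matrix(0, p, ncomp)
  if (used > 0L) {
    Ru <- R[, seq_len(used), drop = FALSE]
    acc <- numeric(p)
    for (a in seq_len(ncomp)) {
      if (a <= used) acc <- acc + Ru[, a] * Q[a]
      B[, a] <- acc
    }
  }
  list(B = B, x_center = xm, y_center = ym, used = used)
}

# Coefficients + intercept at a single component count.
.simpls_fit <- function(X, y, ncomp) {
  path <- .simpls_path(X, y, ncomp)
  b <- path$B[, ncomp]
  list(coefficients = b,
       intercept = path$y_center - sum(path$x_center * b),
       n_components = min(ncomp, max(path$used, 1L)))
}

# Deterministic inner 5-fold CV over 1..ncomp_max, minimizing RMSE.
# Fold assignment is rep_len (no RNG) so that fitting is a pure function
# of its inputs.
.select_ncomp <- function(X, y, ncomp_max, inner_folds = 5L) {
  n <- nrow(X)
  inner_folds <- min(inner_folds, n)
  fold <- rep_len(seq_len(inner_folds), n)
  sse <- numeric(ncomp_max)
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (sum(tr) < 2L || stats::sd(y[tr]) == 0) next
    a_max <- min(ncomp_max, sum(tr) - 1L, ncol(X))
    path <- .simpls_path(X[tr, , drop = FALSE], y[tr], a_max)
    pred <- X[!tr, , drop = FALSE] %*% path$B                  # n_te x a_max
    icept <- path$y_center - drop(crossprod(path$x_center, path$B))
    pred <- sweep(pred, 2L, icept, `+`, check.margin = FALSE)
    err <- (pred - y[!tr])^2
    sse[seq_len(a_max)] <- sse[seq_len(a_max)] + colSums(err)
    if (a_max < ncomp_max) {
      sse[(a_max + 1L):ncomp_max] <- sse[(a_max + 1L):ncomp_max] + sum(err[, a_max])
    }
  }
  which.min(sse)
}

#' Fit a PLSR model (SIMPLS) to connectome features
#'
#' Fits partial least squares regression of a single target on an
#' `subjects x edges` feature matrix. When `n_components` is `NULL` the
#' component count is chosen by a deterministic inner 5-fold
#' cross-validation over `1..max_components`, minimizing RMSE.
#'
#' The returned coefficients are on the raw feature scale: predictions are
#' `intercept + X %*% coefficients` with no further centring, matching the
#' convention of the per-edge BETA weight map used for interpretation and
#' model transfer.
#'
#' @param X Numeric matrix, subjects x edges, no missing values.
#' @param y Numeric target vector, length `nrow(X)`, not constant.
#' @param n_components Number of latent components, or `NULL` for the inner
#'   cross-validation rule. Must lie in `[1, min(nrow(X) - 1, ncol(X))]`.
#' @param max_components Upper bound scanned in auto mode (default 20).
#' @param target_name Stored label for the target.
#' @param atlas Optional atlas; its hash is stored for transfer-time
#'   feature-space checks.
#' @return Object of class `pls_model`: `coefficients`, `intercept`,
#'   `n_components`, `target_name`, `training_n`, `x_center`, `y_center`,
#'   `atlas_hash`.
#' @export
fit_plsr <- function(X, y, n_components = NULL, max_components = 20L,
                     target_name = "y", atlas = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("invalid input: missing values in X or y")
  if (length(y) != nrow(X)) stop("invalid input: length(y) != nrow(X)")
  if (stats::sd(y) == 0) stop("degenerate target: y is constant")
  nc_max <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) {
    scan_max <- min(max_components, nc_max)
    n_components <- .select_ncomp(X, y, scan_max)
  } else {
    if (length(n_components) != 1L || n_components < 1 || n_components > nc_max) {
      stop("invalid parameter: n_components must be in [1, ", nc_max, "]")
    }
    n_components <- as.integer(n_components)
  }
  path <- .simpls_path(X, y, n_components)
  b <- path$B[, n_components]
  structure(list(
    coefficients = b,
    intercept = path$y_center - sum(path$x_center * b),
    n_components = n_components,
    target_name = target_name,
    training_n = nrow(X),
    x_center = path$x_center,
    y_center = path$y_center,
    atlas_hash = if (is.null(atlas)) NULL else atlas_hash(atlas)
  ), class = "pls_model")
}

#' Predict from a fitted PLSR model
#' @param object A `pls_model`.
#' @param newdata Numeric matrix, subjects x edges, same edge ordering as
#'   the training data.
#' @param ... Ignored.
#' @return Numeric vector of predicted scores.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("incompatible feature space: model has ", length(object$coefficients),
         " edges, data has ", ncol(newdata))
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLSR model (SIMPLS)\n",
      "  target:      ", x$target_name, "\n",
      "  components:  ", x$n_components, "\n",
      "  edges:       ", length(x$coefficients), "\n",
      "  training n:  ", x$training_n, "\n", sep = "")
  invisible(x)
}
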