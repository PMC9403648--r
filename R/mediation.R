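# Per-edge mediation of the age -> cognition association through
# functional connectivity: OLS path estimates, bootstrap percentile
# confidence intervals and p-values for the indirect effect, and BH-FDR
# over the top-k weighted edges of a predictive model.

# Path estimates for one edge via three OLS fits sharing the covariate set.
# Returns c(a, b, c_prime, c_total).
.mediation_paths <- function(x, m, y, cov) {
  d1 <- cbind(1, x, cov)
  a <- stats::lm.fit(d1, m)$coefficients[2L]
  d2 <- cbind(1, x, m, cov)
  f2 <- stats::lm.fit(d2, y)$coefficients
  c_total <- stats::lm.fit(d1, y)$coefficients[2L]
  c(a = unname(a), b = unname(f2[3L]), c_prime = unname(f2[2L]),
    c_total = unname(c_total))
}

#' Mediation analysis for a single edge
#'
#' Estimates the paths of the simple mediation model with age (`x`) as the
#' independent variable, one connectivity edge (`m`) as the mediator and a
#' cognitive score (`y`) as the outcome, with optional covariates (e.g.
#' gender and mean FD) in every regression: `a` from `m ~ x + cov`, `b` and
#' the direct effect `c_prime` from `y ~ x + m + cov`, the total effect
#' `c_total` from `y ~ x + cov`. The indirect effect is `a * b`
#' (`a*b + c_prime = c_total` exactly for OLS). Its confidence interval and
#' two-sided p come from subject-level bootstrap resampling.
#'
#' @param x Independent variable (age), length n >= 10.
#' @param m Mediator (edge values).
#' @param y Outcome (cognitive score).
#' @param covariates Optional covariate vector/matrix; the design must be
#'   full rank.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param conf_level Percentile CI level (default 0.95).
#' @param total_tol Proportion mediated `(a*b)/c_total` is reported only
#'   when `|c_total|` exceeds this tolerance; otherwise it is `NA` with
#'   `proportion_defined = FALSE`.
#' @return List with `a_path`, `b_path`, `c_prime`, `c_total`, `indirect`,
#'   `ci_low`, `ci_high`, `p_boot`, `proportion_mediated`,
#'   `proportion_defined`, `n_boot`.
#' @export
mediate_edge <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                         seed = 1L, conf_level = 0.95, total_tol = 1e-8) {
  set.seed(seed)
  .mediate_core(x, m, y, covariates, n_boot, conf_level, total_tol)
}

# Core that consumes the current RNG stream (shared with mediate_topk).
.mediate_core <- function(x, m, y, covariates, n_boot, conf_level = 0.95,
                          total_tol = 1e-8) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("invalid input: length mismatch")
  if (n < 10) stop("invalid input: need at least 10 observations")
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  d_check <- cbind(1, x, cov)
  if (qr(d_check)$rank < ncol(d_check)) {
    stop("collinearity error: covariates are rank deficient with the predictor")
  }
  est <- .mediation_paths(x, m, y, cov)
  indirect <- est["a"] * est["b"]
  ab_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- .mediation_paths(x[idx], m[idx], y[idx],
                           if (is.null(cov)) NULL else cov[idx, , drop = FALSE])
    ab_boot[b] <- pb["a"] * pb["b"]
  }
  alpha <- 1 - conf_level
  ci <- stats::quantile(ab_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p_boot <- min(1, 2 * min((1 + sum(ab_boot <= 0)) / (1 + n_boot),
                           (1 + sum(ab_boot >= 0)) / (1 + n_boot)))
  defined <- abs(est["c_total"]) > total_tol
  list(a_path = unname(est["a"]), b_path = unname(est["b"]),
       c_prime = unname(est["c_prime"]), c_total = unname(est["c_total"]),
       indirect = unname(indirect), ci_low = ci[1L], ci_high = ci[2L],
       p_boot = p_boot,
       proportion_mediated = if (defined) unname(indirect / est["c_total"]) else NA_real_,
       proportion_defined = unname(defined), n_boot = as.integer(n_boot))
}

#' Mediation over the top-k weighted edges of a predictive model
#'
#' Selects the `k` edges with the largest (`sign = "positive"`) or smallest
#' (`sign = "negative"`) predictive weights (ties broken by edge index),
#' runs [mediate_edge()] for each with age as predictor and the cognitive
#' score as outcome, and applies Benjamini-Hochberg FDR across exactly the
#' `k` tests.
#'
#' @param weight_map Connection-level `weight_map` or numeric edge vector
#'   aligned with the columns of `X`.
#' @param X Subjects x edges matrix of mediator values.
#' @param x Age vector.
#' @param y Cognitive outcome vector.
#' @param covariates Optional covariates for every regression.
#' @param k Number of edges tested (must not exceed the edge count).
#' @param sign `"positive"` or `"negative"` weight tail.
#' @param n_boot Bootstrap iterations per edge.
#' @param seed Integer seed.
#' @param alpha FDR threshold for `n_significant` (default 0.05).
#' @return List with `records` (data.frame, one row per tested edge:
#'   `edge_id`, paths, `indirect`, CI, `p_boot`, `q_value`,
#'   `proportion_mediated`), `n_significant`, `prop_range` (min and max
#'   proportion mediated among significant edges), `k`, `sign`.
#' @export
mediate_topk <- function(weight_map, X, x, y, covariates = NULL, k = 100L,
                         sign = c("positive", "negative"), n_boot = 10000L,
                         seed = 1L, alpha = 0.05) {
  sign <- match.arg(sign)
  w <- .map_values(weight_map)
  X <- as.matrix(X)
  if (length(w) != ncol(X)) stop("shape error: weight map not aligned with X")
  if (k > length(w)) stop("invalid parameter: k exceeds the edge count")
  ord <- if (sign == "positive") {
    order(-w, seq_along(w))
  } else {
    order(w, seq_along(w))
  }
  edge_ids <- ord[seq_len(k)]
  set.seed(seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    e <- edge_ids[i]
    rec <- .mediate_core(x, X[, e], y, covariates, n_boot)
    rows[[i]] <- data.frame(edge_id = e, weight = w[e], a_path = rec$a_path,
                            b_path = rec$b_path, c_prime = rec$c_prime,
                            c_total = rec$c_total, indirect = rec$indirect,
                            ci_low = rec$ci_low, ci_high = rec$ci_high,
                            p_boot = rec$p_boot,
                            proportion_mediated = rec$proportion_mediated)
  }
  records <- do.call(rbind, rows)
  records$q_value <- stats::p.adjust(records$p_boot, method = "BH")
  sig <- records$q_value < alpha
  props <- records$proportion_mediated[sig]
  props <- props[is.finite(props)]
  list(records = records,
       n_significant = sum(sig),
       prop_range = if (length(props)) range(props) else c(NA_real_, NA_real_),
       k = as.integer(k), sign = sign, alpha = alpha)
}
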