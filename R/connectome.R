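# Connectome construction and edge bookkeeping.
#
# Canonical edge layout used everywhere in the package: the upper triangle
# of the node x node matrix enumerated row-major, i.e. (1,2), (1,3), ...,
# (1,n), (2,3), ..., (n-1,n).  For a symmetric matrix this is exactly
# m[lower.tri(m)] in R's column-major storage.

#' Number of unique edges in an undirected connectome
#'
#' @param n_nodes Number of nodes (parcels); must be a single integer >= 2.
#' @return Integer, `n_nodes * (n_nodes - 1) / 2`. A 246-node parcellation
#'   yields 30135 unique edges.
#' @examples
#' n_edges(246)
#' @export
n_edges <- function(n_nodes) {
  if (length(n_nodes) != 1L || is.na(n_nodes) || !is.numeric(n_nodes) ||
      n_nodes != round(n_nodes) || n_nodes < 2) {
    stop("invalid input: `n_nodes` must be a single integer >= 2")
  }
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Node pairs of the canonical edge ordering
#'
#' @param n_nodes Number of nodes.
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per edge,
#'   rows in the canonical row-major upper-triangle order.
#' @export
edge_pairs <- function(n_nodes) {
  n_edges(n_nodes) # validates
  n <- as.integer(n_nodes)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

#' Position of node pair (i, j) in the canonical edge vector
#'
#' @param i,j Node indices (1-based, `i < j`), vectorized.
#' @param n_nodes Number of nodes.
#' @return Integer vector of positions in the edge vector.
#' @export
edge_index <- function(i, j, n_nodes) {
  n_edges(n_nodes)
  if (any(i >= j) || any(i < 1) || any(j > n_nodes)) {
    stop("invalid input: need 1 <= i < j <= n_nodes")
  }
  as.integer((i - 1) * n_nodes - i * (i - 1) / 2 + (j - i))
}

#' Vectorize a symmetric matrix to the canonical edge vector
#'
#' @param m Symmetric numeric matrix (tolerance 1e-8 on asymmetry).
#' @param tol Symmetry tolerance.
#' @return Numeric vector of the upper-triangle entries in canonical order.
#' @export
vectorize <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("invalid input: `m` must be a square matrix")
  }
  if (max(abs(m - t(m))) > tol) {
    stop("invalid input: matrix is not symmetric within tolerance ", tol)
  }
  m[lower.tri(m)]
}

#' Rebuild the symmetric matrix from a canonical edge vector
#'
#' The diagonal is restored as zeros.
#'
#' @param edges Numeric edge vector of length `n * (n - 1) / 2`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
devectorize <- function(edges) {
  e <- length(edges)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("invalid input: length ", e, " is not a triangular number")
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- edges
  m + t(m)
}

#' Fisher z-transform with clipping
#'
#' Correlations are clipped to `|r| <= 1 - 1e-7` before `atanh` so that
#' perfect (anti)correlations map to large finite values and ordering is
#' preserved.
#'
#' @param r Numeric vector of correlations.
#' @param clip Clipping bound, default `1 - 1e-7`.
#' @return `atanh` of the clipped correlations.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Inverse Fisher transform
#' @param z Numeric vector of Fisher-z values.
#' @return `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Compute a connectome from a parcellated time series
#'
#' Pairwise Pearson correlations between all node time series, Fisher
#' z-transformed, returned as the canonical upper-triangle edge vector.
#'
#' @param ts Numeric matrix, nodes x timepoints, at least 3 timepoints.
#' @return Numeric edge vector of Fisher-z correlations, length
#'   `n_edges(nrow(ts))`.
#' @export
compute_connectome <- function(ts) {
  if (!is.matrix(ts) || ncol(ts) < 3) {
    stop("invalid input: `ts` must be a nodes x timepoints matrix with >= 3 timepoints")
  }
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("degenerate input: zero-variance node(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  fisher_z(r[lower.tri(r)])
}
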