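# Weight-map interpretation: averaging fold-level coefficient vectors and
# summarizing them at the connection, node and network level, plus
# permutation-based overlap between two models' maps.

#' Construct a weight map
#'
#' @param values Numeric vector (length must match the level: edges for
#'   `connection`, nodes for `node`, network pairs for `network`).
#' @param level One of `"connection"`, `"node"`, `"network"`.
#' @param n_models_averaged How many fold/bootstrap models were averaged.
#' @param source Optional free-form metadata (e.g. target name).
#' @return Object of class `weight_map`.
#' @export
weight_map <- function(values, level = c("connection", "node", "network"),
                       n_models_averaged = 1L, source = NULL) {
  level <- match.arg(level)
  structure(list(values = as.numeric(values), level = level,
                 n_models_averaged = as.integer(n_models_averaged),
                 source = source),
            class = "weight_map")
}

.map_values <- function(x) if (inherits(x, "weight_map")) x$values else as.numeric(x)

#' Average fold-level weight maps into a connection-level map
#'
#' @param fold_maps Either an `edges x n_models` matrix (as stored in a
#'   `cv_result`) or a list of equal-length coefficient vectors.
#' @param source Optional metadata.
#' @return Connection-level `weight_map`, elementwise mean, with
#'   `n_models_averaged` recorded.
#' @export
average_maps <- function(fold_maps, source = NULL) {
  if (is.list(fold_maps) && !is.data.frame(fold_maps)) {
    lens <- lengths(fold_maps)
    if (length(fold_maps) == 0) stop("invalid input: empty map list")
    if (length(unique(lens)) != 1) stop("shape error: maps have mixed lengths")
    fold_maps <- do.call(cbind, fold_maps)
  }
  fold_maps <- as.matrix(fold_maps)
  weight_map(rowMeans(fold_maps), "connection",
             n_models_averaged = ncol(fold_maps), source = source)
}

#' Node-level summary of a connection-level weight map
#'
#' Each node's value is the (signed, by default) sum of the weights of its
#' incident edges; summing over nodes double-counts every edge, so the node
#' total equals twice the edge total.
#'
#' @param map Connection-level `weight_map` or numeric edge vector.
#' @param atlas Atlas aligned with the map.
#' @param absolute Sum `|w|` instead of `w` (default `FALSE`).
#' @return Node-level `weight_map` of length `nrow(atlas)`.
#' @export
node_summary <- function(map, atlas, absolute = FALSE) {
  v <- .map_values(map)
  atlas <- validate_atlas(atlas)
  n <- nrow(atlas)
  if (length(v) != n_edges(n)) {
    stop("shape error: map has ", length(v), " edges but atlas implies ",
         n_edges(n))
  }
  if (absolute) v <- abs(v)
  ep <- edge_pairs(n)
  vals <- as.vector(rowsum(c(v, v), c(ep[, 1L], ep[, 2L])))
  weight_map(vals, "node",
             n_models_averaged = if (inherits(map, "weight_map")) map$n_models_averaged else 1L)
}

#' Network-level summary of a connection-level weight map
#'
#' For every network pair (within-network cells included), weights of all
#' member edges are summed and normalized by the pair's edge count, giving
#' a size-corrected mean; positive and negative weights are additionally
#' summarized separately (each sum divided by the pair's total edge count)
#' to show their relative contributions.
#'
#' @param map Connection-level `weight_map` or numeric edge vector.
#' @param atlas Atlas aligned with the map.
#' @return List with `cells` (data.frame `net_a`, `net_b`, `mean_weight`,
#'   `pos_norm`, `neg_norm`, `n_edges`, canonical pair order) and `map`
#'   (network-level `weight_map` of the mean values).
#' @export
network_summary <- function(map, atlas) {
  v <- .map_values(map)
  ec <- edge_classes(atlas)
  if (length(v) != length(ec$edge_class)) {
    stop("shape error: map has ", length(v), " edges but atlas implies ",
         length(ec$edge_class))
  }
  np <- nrow(ec$pairs)
  agg <- function(x) {
    s <- rowsum(x, ec$edge_class) # empty classes (0-edge pairs) are absent
    out <- numeric(np)
    out[as.integer(rownames(s))] <- s
    out
  }
  tot <- agg(v)
  pos <- agg(pmax(v, 0))
  neg <- agg(pmin(v, 0))
  cnt <- ec$pairs$n_edges
  cells <- ec$pairs
  cells$mean_weight <- ifelse(cnt > 0, tot / cnt, NA_real_)
  cells$pos_norm <- ifelse(cnt > 0, pos / cnt, NA_real_)
  cells$neg_norm <- ifelse(cnt > 0, neg / cnt, NA_real_)
  cells <- cells[, c("net_a", "net_b", "mean_weight", "pos_norm", "neg_norm",
                     "n_edges")]
  nm <- if (inherits(map, "weight_map")) map$n_models_averaged else 1L
  list(cells = cells,
       map = weight_map(cells$mean_weight, "network", n_models_averaged = nm))
}

#' Overlap between two weight maps
#'
#' Pearson correlation between two same-level maps, with a permutation null
#' built by shuffling the entries of the second map and recomputing the
#' correlation each iteration; two-sided p via the add-one estimator.
#'
#' @param map_a,map_b `weight_map`s (or numeric vectors) of the same level
#'   and length.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `level`, `r`, `p`, `n_perm`, `null_values`.
#' @export
overlap <- function(map_a, map_b, n_perm = 10000L, seed = 1L) {
  if (inherits(map_a, "weight_map") && inherits(map_b, "weight_map") &&
      map_a$level != map_b$level) {
    stop("incompatible maps: levels differ (", map_a$level, " vs ",
         map_b$level, ")")
  }
  a <- .map_values(map_a)
  b <- .map_values(map_b)
  if (length(a) != length(b)) stop("incompatible maps: lengths differ")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]
  b <- b[ok]
  r <- stats::cor(a, b)
  set.seed(seed)
  null_values <- vapply(seq_len(n_perm),
                        function(i) stats::cor(a, b[sample.int(length(b))]),
                        numeric(1))
  list(level = if (inherits(map_a, "weight_map")) map_a$level else "connection",
       r = r, p = perm_pvalue(r, null_values, two_sided = TRUE),
       n_perm = as.integer(n_perm), null_values = null_values)
}
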