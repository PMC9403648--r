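# Atlas handling: node -> network assignment and network-pair bookkeeping.
#
# An atlas is a data.frame with columns `node_id`, `node_label`,
# `network_label`; nodes appear in connectome order. Network order is the
# order of first appearance in the table and fixes the canonical ordering
# of the K*(K+1)/2 network pairs (row-major over the upper triangle of the
# K x K network grid, diagonal included).

#' Construct an atlas from network sizes
#'
#' @param network_sizes Integer vector of nodes per network (all >= 1).
#' @param network_labels Character labels, one per network; defaults to
#'   `net1`, `net2`, ...
#' @param node_labels Optional node labels; default `N001`, ...
#' @return Atlas data.frame with class `c("fc_atlas", "data.frame")`.
#' @export
make_atlas <- function(network_sizes, network_labels = NULL, node_labels = NULL) {
  if (length(network_sizes) < 1 || any(network_sizes < 1) ||
      any(network_sizes != round(network_sizes))) {
    stop("invalid atlas: `network_sizes` must be positive integers")
  }
  k <- length(network_sizes)
  if (is.null(network_labels)) network_labels <- paste0("net", seq_len(k))
  if (length(network_labels) != k || anyDuplicated(network_labels)) {
    stop("invalid atlas: need one unique label per network")
  }
  n <- sum(network_sizes)
  if (is.null(node_labels)) node_labels <- sprintf("N%03d", seq_len(n))
  atlas <- data.frame(
    node_id = seq_len(n),
    node_label = node_labels,
    network_label = rep(network_labels, times = network_sizes),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("fc_atlas", "data.frame")
  validate_atlas(atlas)
}

#' Validate an atlas table
#'
#' @param atlas Data.frame with columns `node_id`, `node_label`,
#'   `network_label`.
#' @return The atlas, invisibly classed as `fc_atlas`.
#' @export
validate_atlas <- function(atlas) {
  req <- c("node_id", "node_label", "network_label")
  missing_cols <- setdiff(req, names(atlas))
  if (length(missing_cols)) {
    stop("invalid atlas: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- is.na(atlas$network_label) | atlas$network_label == ""
  if (any(bad)) {
    stop("invalid atlas: node(s) without a network assignment: ",
         paste(atlas$node_id[bad], collapse = ", "))
  }
  if (anyDuplicated(atlas$node_id)) stop("invalid atlas: duplicated node_id")
  if (!inherits(atlas, "fc_atlas")) class(atlas) <- c("fc_atlas", "data.frame")
  atlas
}

#' Network labels of an atlas in canonical (first-appearance) order
#' @param atlas An atlas.
#' @return Character vector of network labels.
#' @export
networks <- function(atlas) unique(atlas$network_label)

#' Canonical ordering of network pairs
#'
#' Row-major over the upper triangle (diagonal included) of the K x K
#' network grid: (1,1), (1,2), ..., (1,K), (2,2), ..., (K,K).
#'
#' @param atlas An atlas (or a character vector of network labels).
#' @return Data.frame with columns `net_a`, `net_b`, one row per pair;
#'   `K*(K+1)/2` rows (36 for 8 networks).
#' @export
network_pairs <- function(atlas) {
  nets <- if (is.character(atlas)) atlas else networks(atlas)
  k <- length(nets)
  a <- rep.int(seq_len(k), times = k:1)
  b <- sequence(k:1, from = seq_len(k))
  data.frame(net_a = nets[a], net_b = nets[b], stringsAsFactors = FALSE)
}

# Row-major pair index for network indices lo <= hi among K networks.
.pair_index <- function(lo, hi, k) {
  as.integer((lo - 1) * (k + 1) - lo * (lo - 1) / 2 + (hi - lo + 1))
}

#' Classify every edge by its network pair
#'
#' @param atlas An atlas covering all nodes of the connectome.
#' @return List with `edge_class` (integer pair index per edge, canonical
#'   edge order), `pairs` (data.frame `net_a`, `net_b`, `n_edges`), and
#'   `networks` (labels in canonical order). Per-pair counts sum to the
#'   total edge count.
#' @export
edge_classes <- function(atlas) {
  atlas <- validate_atlas(atlas)
  n <- nrow(atlas)
  if (n < 2) stop("invalid atlas: need at least 2 nodes")
  nets <- networks(atlas)
  k <- length(nets)
  node_net <- match(atlas$network_label, nets)
  ep <- edge_pairs(n)
  na <- node_net[ep[, 1L]]
  nb <- node_net[ep[, 2L]]
  lo <- pmin(na, nb)
  hi <- pmax(na, nb)
  cls <- .pair_index(lo, hi, k)
  pairs <- network_pairs(nets)
  pairs$n_edges <- tabulate(cls, nbins = nrow(pairs))
  list(edge_class = cls, pairs = pairs, networks = nets)
}

#' Read an atlas TSV
#'
#' Expected columns: `node_id`, `node_label`, `network_label`; nodes in
#' connectome order.
#'
#' @param path Path to a tab-delimited atlas file.
#' @return Validated atlas data.frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  atlas <- as.data.frame(data.table::fread(path, sep = "\t",
                                           colClasses = list(character = "network_label")))
  tryCatch(validate_atlas(atlas),
           error = function(e) stop("invalid atlas in '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write an atlas TSV
#' @param atlas An atlas.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- validate_atlas(atlas)
  data.table::fwrite(as.data.frame(atlas)[, c("node_id", "node_label", "network_label")],
                     path, sep = "\t")
  invisible(path)
}

#' The packaged 246-node, 8-network atlas
#'
#' A synthetic stand-in for a 246-parcel atlas whose nodes are grouped into
#' the eight canonical networks (VIS, SMN, DAN, VAN, LIM, FPN, DMN, SUB):
#' 210 cortical nodes with plausible network sizes plus 36 subcortical
#' nodes. The node-to-network assignment is constructed, not taken from any
#' published parcellation table; it reproduces the structural counts (246
#' nodes, 30135 edges, 36 network pairs) used throughout the package.
#'
#' @return Atlas data.frame with 246 rows.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "brainnetome246_8net_synthetic.tsv",
                      package = "connpred", mustWork = TRUE)
  read_atlas(path)
}

#' Deterministic fingerprint of an atlas
#'
#' Used to guard frozen-model transfer against applying a model to features
#' from a different parcellation: the hash of the training atlas is stored
#' in the model and checked on application.
#'
#' @param atlas An atlas.
#' @return Character scalar (hex digits).
#' @export
atlas_hash <- function(atlas) {
  atlas <- validate_atlas(atlas)
  s <- paste(atlas$node_id, atlas$network_label, sep = ":", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%09x", h)
}
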