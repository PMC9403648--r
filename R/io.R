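# Delimited-text readers and writers for the pipeline's tables. All files
# are UTF-8 TSV with explicit identifier columns; read(write(x)) round
# trips values bitwise (doubles serialized with 17 significant digits).

# fwrite with doubles rendered at full round-trip precision.
.write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a phenotype table
#'
#' Columns: `subject_id`, `age`, `gender`, `mean_fd`, one column per
#' cognitive metric.
#'
#' @param cohort Phenotype data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  if (!all(c("subject_id", "age") %in% names(cohort))) {
    stop("schema error in phenotype table: need columns subject_id, age")
  }
  .write_tsv_full(cohort, path)
}

#' Read a phenotype table
#' @param path Path to a TSV written by [write_phenotypes()].
#' @return Data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  for (col in c("subject_id", "age")) {
    if (!col %in% names(out)) {
      stop("schema error in '", path, "': missing column '", col, "'")
    }
  }
  out
}

#' Write a subjects x edges connectome matrix
#'
#' One row per subject; first column `subject_id`, remaining columns the
#' canonical edge vector (`e1`, `e2`, ...).
#'
#' @param connectomes Numeric matrix with subject ids as rownames (or a
#'   `subject_id` attribute supplied via `ids`).
#' @param path Output path.
#' @param ids Optional subject ids overriding rownames.
#' @return `path`, invisibly.
#' @export
write_edge_matrix <- function(connectomes, path, ids = rownames(connectomes)) {
  connectomes <- as.matrix(connectomes)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(connectomes)))
  mat <- as.data.frame(connectomes)
  names(mat) <- paste0("e", seq_len(ncol(connectomes)))
  .write_tsv_full(cbind(data.frame(subject_id = ids), mat), path)
}

#' Read a subjects x edges connectome matrix
#' @param path Path to a TSV written by [write_edge_matrix()].
#' @return Numeric matrix with subject ids as rownames.
#' @export
read_edge_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"subject_id" %in% names(dt)) {
    stop("schema error in '", path, "': missing column 'subject_id'")
  }
  ids <- dt$subject_id
  m <- as.matrix(dt[, setdiff(names(dt), "subject_id"), drop = FALSE])
  rownames(m) <- ids
  m
}

#' Write a weight map as TSV
#'
#' Connection-level maps get columns `edge_id`, `node_i`, `node_j`,
#' `weight`; node-level maps `node_id`, `weight`; network-level maps the
#' cells table from [network_summary()].
#'
#' @param map A `weight_map` (connection or node level).
#' @param atlas Atlas used for the identifier columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(map, atlas, path) {
  stopifnot(inherits(map, "weight_map"))
  atlas <- validate_atlas(atlas)
  if (map$level == "connection") {
    ep <- edge_pairs(nrow(atlas))
    df <- data.frame(edge_id = seq_along(map$values), node_i = ep[, 1L],
                     node_j = ep[, 2L], weight = map$values)
  } else if (map$level == "node") {
    df <- data.frame(node_id = atlas$node_id, weight = map$values)
  } else {
    np <- network_pairs(atlas)
    df <- data.frame(net_a = np$net_a, net_b = np$net_b, weight = map$values)
  }
  .write_tsv_full(df, path)
}
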