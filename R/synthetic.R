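# Synthetic adult-lifespan cohorts with network-structured connectome
# effects. The generator plants the qualitative structure the analysis is
# designed to detect: within-network connections of "segregating" networks
# weaken with age and support cognition, limbic within-network connections
# strengthen with age, and sensorimotor-to-associative between-network
# connections strengthen with age while predicting lower cognition; a
# lognormal head-motion confound is mildly age-correlated.

#' Default per-edge effect map
#'
#' Builds the `(beta_age, beta_cog)` loading pair for every edge from the
#' atlas's network structure. With the canonical 8-network labels:
#' within-network edges of DMN, VAN and SMN load negatively on age and
#' positively on cognition (the shared, opposite-signed core); within-SUB
#' edges are age-dominant (negative age loading, no cognition loading);
#' within-DAN edges are cognition-specific (positive cognition loading, no
#' age loading); within-LIM edges load positively on age and negatively on
#' cognition; between-network edges linking SMN to DAN, VAN and FPN load
#' positively on age and negatively on cognition; all other edges carry
#' zero loading. For atlases without those labels the roles are assigned by
#' network position (first networks shared, last network limbic-like when
#' K >= 3, network 1 the between-network hub when K >= 4). Magnitudes carry
#' independent per-edge jitter; the age and cognition loading vectors are
#' negatively correlated by construction.
#'
#' The default amplitudes are calibrated so that, at the default cohort
#' settings (n = 300, noise_sd = 0.5), age is the best-predicted target and
#' cognition clearly predictable but weaker, mirroring the accuracy
#' ordering seen in adult-lifespan connectome studies, while per-edge
#' loadings remain individually detectable.
#'
#' @param atlas An atlas with at least 2 networks.
#' @param seed Integer seed for the magnitude jitter.
#' @param amplitude Base age-loading magnitude in Fisher-z units per SD of
#'   standardized age (default 0.12).
#' @param cog_amplitude Base cognition-loading magnitude (default 0.07).
#' @return Numeric matrix, edges x 2, columns `beta_age`, `beta_cog`.
#' @export
default_effect_map <- function(atlas, seed = 1L, amplitude = 0.12,
                               cog_amplitude = 0.07) {
  ec <- edge_classes(atlas)
  nets <- ec$networks
  k <- length(nets)
  if (k < 2) stop("invalid atlas: effect map needs at least 2 networks")
  std <- c("SMN", "DMN", "VAN")
  if (all(std %in% nets)) {
    seg <- intersect(c("DMN", "VAN", "SMN"), nets)
    age_only <- intersect("SUB", nets)
    cog_only <- intersect("DAN", nets)
    lim <- intersect("LIM", nets)
    hub <- "SMN"
    assoc <- intersect(c("DAN", "VAN", "FPN"), nets)
  } else {
    seg <- nets[seq_len(max(1L, min(3L, k - 1L)))]
    age_only <- character(0)
    cog_only <- character(0)
    lim <- if (k >= 3) nets[k] else character(0)
    hub <- if (k >= 4) nets[1L] else character(0)
    assoc <- if (k >= 4) nets[2:min(3L, k - 1L)] else character(0)
  }
  pairs <- ec$pairs
  cls_a <- pairs$net_a[ec$edge_class]
  cls_b <- pairs$net_b[ec$edge_class]
  within <- cls_a == cls_b
  is_seg <- within & cls_a %in% seg
  is_age <- within & cls_a %in% age_only
  is_cog <- within & cls_a %in% cog_only
  is_lim <- within & cls_a %in% lim
  is_hub <- !within &
    ((cls_a %in% hub & cls_b %in% assoc) | (cls_b %in% hub & cls_a %in% assoc))
  e <- length(ec$edge_class)
  set.seed(seed)
  u_age <- stats::runif(e, 0.75, 1.25) * amplitude
  u_cog <- stats::runif(e, 0.75, 1.25) * cog_amplitude
  beta_age <- numeric(e)
  beta_cog <- numeric(e)
  beta_age[is_seg] <- -u_age[is_seg]
  beta_cog[is_seg] <- u_cog[is_seg]
  beta_age[is_age] <- -u_age[is_age]
  beta_cog[is_cog] <- u_cog[is_cog]
  beta_age[is_lim] <- u_age[is_lim]
  beta_cog[is_lim] <- -u_cog[is_lim]
  beta_age[is_hub] <- u_age[is_hub]
  beta_cog[is_hub] <- -u_cog[is_hub]
  cbind(beta_age = beta_age, beta_cog = beta_cog)
}

#' Specification of a synthetic cohort
#'
#' @param atlas Atlas defining nodes and networks.
#' @param n_subjects Cohort size (default 300).
#' @param age_range Years, low and high (default 19-89, an adult-lifespan
#'   cohort; ages drawn uniform).
#' @param age_cog_slope Standardized slope of cognition on age, shared by
#'   all metrics (default -0.6: scores decline with age).
#' @param edge_effect_map Edges x 2 matrix of `(beta_age, beta_cog)`
#'   loadings; defaults to [default_effect_map()] on this atlas and seed.
#' @param confound_slope Edge response to head motion, z-units per mm mean
#'   FD (default 0.15).
#' @param noise_sd Edge noise SD in z-units (default 0.5).
#' @param baseline Baseline edge value in z-units (default 0.25).
#' @param metric_names Names of the cognitive metrics (default: the eight
#'   task domains).
#' @param missing_rate Per-metric missingness probability (default 0,
#'   complete data); at least one metric is always kept per subject.
#' @param seed Default seed for [simulate_cohort()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(atlas, n_subjects = 300L, age_range = c(19, 89),
                           age_cog_slope = -0.6, edge_effect_map = NULL,
                           confound_slope = 0.15, noise_sd = 0.5,
                           baseline = 0.25,
                           metric_names = c("gF", "force_matching", "hotel",
                                            "motor_learning", "TOT", "VSTM",
                                            "face_recognition",
                                            "emotion_recognition"),
                           missing_rate = 0, seed = 1L) {
  atlas <- validate_atlas(atlas)
  n_nodes <- nrow(atlas)
  if (n_nodes < 2) stop("invalid spec: need at least 2 nodes")
  if (n_subjects < 3) stop("invalid spec: need at least 3 subjects")
  if (noise_sd < 0) stop("invalid spec: noise_sd must be >= 0")
  if (abs(age_cog_slope) > 1) stop("invalid spec: |age_cog_slope| must be <= 1")
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop("invalid spec: age_range must be (low, high) with low < high")
  }
  if (is.null(edge_effect_map)) edge_effect_map <- default_effect_map(atlas, seed)
  edge_effect_map <- as.matrix(edge_effect_map)
  if (nrow(edge_effect_map) != n_edges(n_nodes) || ncol(edge_effect_map) != 2) {
    stop("invalid spec: edge_effect_map must be n_edges x 2")
  }
  structure(list(atlas = atlas, n_subjects = as.integer(n_subjects),
                 age_range = age_range, age_cog_slope = age_cog_slope,
                 edge_effect_map = edge_effect_map,
                 confound_slope = confound_slope, noise_sd = noise_sd,
                 baseline = baseline, metric_names = metric_names,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a cohort of phenotypes and connectomes
#'
#' Ages are uniform over the spec's range. Each cognitive metric is
#' `age_cog_slope * std(age)` plus an independent Gaussian residual scaled
#' so scores are approximately unit variance. Mean framewise displacement
#' is lognormal and mildly age-correlated. Each edge value is
#' `baseline + beta_age * std(age) + beta_cog * std(cog_resid) +
#' confound_slope * mean_fd + N(0, noise_sd)`, where `cog_resid` is the
#' age-independent component of the primary (first) cognitive metric.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (default `spec$seed`); output is reproducible
#'   bitwise from `(spec, seed)`.
#' @return List with `cohort` (data.frame: `subject_id`, `age`, `gender`,
#'   `mean_fd`, one column per metric) and `connectomes`
#'   (subjects x edges matrix of Fisher-z values, canonical edge order).
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  std_age <- (age - mean(age)) / stats::sd(age)
  mean_fd <- exp(stats::rnorm(n, log(0.12) + 0.2 * std_age, 0.35))
  gender <- stats::rbinom(n, 1L, 0.5)
  resid_sd <- sqrt(1 - spec$age_cog_slope^2)
  m <- length(spec$metric_names)
  resid <- matrix(stats::rnorm(n * m, 0, resid_sd), n, m)
  scores <- spec$age_cog_slope * std_age + resid
  colnames(scores) <- spec$metric_names
  cog_resid <- resid[, 1L]
  std_cr <- (cog_resid - mean(cog_resid)) / stats::sd(cog_resid)
  e <- nrow(spec$edge_effect_map)
  edges <- spec$baseline +
    tcrossprod(std_age, spec$edge_effect_map[, 1L]) +
    tcrossprod(std_cr, spec$edge_effect_map[, 2L]) +
    spec$confound_slope * mean_fd
  if (spec$noise_sd > 0) {
    edges <- edges + matrix(stats::rnorm(n * e, 0, spec$noise_sd), n, e)
  }
  if (spec$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    all_gone <- rowSums(!drop_mask) == 0
    drop_mask[all_gone, 1L] <- FALSE
    scores[drop_mask] <- NA_real_
  }
  ids <- sprintf("S%04d", seq_len(n))
  rownames(edges) <- ids
  cohort <- data.frame(subject_id = ids, age = age, gender = gender,
                       mean_fd = mean_fd, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(scores))
  list(cohort = cohort, connectomes = edges)
}

#' Simulate a parcellated time series realizing a target connectome
#'
#' The target edge vector (Fisher z) is back-transformed to correlations,
#' repaired to the nearest valid correlation matrix by eigenvalue clipping
#' and diagonal rescaling, and sampled as independent multivariate-normal
#' timepoints; the sample correlation matrix converges to the target as
#' the number of timepoints grows.
#'
#' @param target Edge vector of Fisher-z correlations (canonical order).
#' @param n_timepoints Number of timepoints (>= 2).
#' @param seed Integer seed.
#' @param repair_tol Maximum absolute change to any correlation allowed by
#'   the positive-semidefinite repair (default 0.05); a target needing more
#'   is rejected as invalid.
#' @return Numeric matrix, nodes x timepoints.
#' @export
simulate_timeseries <- function(target, n_timepoints, seed = 1L,
                                repair_tol = 0.05) {
  if (n_timepoints < 2) stop("invalid input: need >= 2 timepoints")
  r0 <- devectorize(fisher_z_inv(target))
  diag(r0) <- 1
  es <- eigen(r0, symmetric = TRUE)
  ev <- pmax(es$values, 1e-8)
  r1 <- es$vectors %*% (ev * t(es$vectors))
  d <- 1 / sqrt(diag(r1))
  r1 <- r1 * tcrossprod(d)
  if (max(abs(r1 - r0)) > repair_tol) {
    stop("invalid target: not repairable to a valid correlation matrix within ",
         repair_tol)
  }
  n <- nrow(r1)
  cf <- chol(r1 + diag(1e-10, n))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  t(z %*% cf)
}
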