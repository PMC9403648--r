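# Shared fixtures, built in code and cached for the duration of the run.

canonical_networks <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN", "SUB")

# Small 8-network atlas with `per` nodes per network.
atlas8 <- function(per = 5L) {
  make_atlas(rep(per, 8L), canonical_networks)
}

# 60-node 8-network atlas with sizes proportional to the packaged default.
atlas60 <- function() {
  make_atlas(c(VIS = 7, SMN = 9, DAN = 6, VAN = 6, LIM = 6, FPN = 7,
               DMN = 10, SUB = 9), canonical_networks)
}

.fixture_env <- new.env(parent = emptyenv())

# Main study-scale cohort: 300 subjects, 60 nodes, default generator
# settings (noise_sd 0.5, age-cognition slope -0.6), seed 42.
fixture_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    at <- atlas60()
    sp <- synthetic_spec(at, n_subjects = 300L, seed = 42L)
    .fixture_env$atlas <- at
    .fixture_env$spec <- sp
    .fixture_env$coh <- simulate_cohort(sp)
  }
  list(atlas = .fixture_env$atlas, spec = .fixture_env$spec,
       cohort = .fixture_env$coh$cohort, X = .fixture_env$coh$connectomes)
}

# A second cohort from the same generator, new seed (external validation).
fixture_cohort_external <- function() {
  if (is.null(.fixture_env$ext)) {
    fx <- fixture_cohort()
    .fixture_env$ext <- simulate_cohort(fx$spec, seed = 43L)
  }
  .fixture_env$ext
}

# Sample vectors with exact zero mean, unit sd and exact zero pairwise
# sample correlation; used to construct exact-correlation fixtures.
orthonormal_pair <- function(n, seed = 1L) {
  set.seed(seed)
  u <- scale(rnorm(n))[, 1L]
  w <- rnorm(n)
  w <- resid(lm(w ~ u))
  w <- scale(w)[, 1L]
  list(u = u, w = w)
}
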