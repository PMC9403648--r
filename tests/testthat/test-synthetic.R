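test_that("default effect map has the planted network sign structure", {
  a <- atlas8(5) # 8 networks, 40 nodes
  em <- default_effect_map(a, seed = 7)
  ec <- edge_classes(a)
  pa <- ec$pairs$net_a[ec$edge_class]
  pb <- ec$pairs$net_b[ec$edge_class]
  within <- pa == pb
  seg <- within & pa %in% c("DMN", "VAN", "SMN")
  sub <- within & pa == "SUB"
  dan <- within & pa == "DAN"
  lim <- within & pa == "LIM"
  hub <- !within & ((pa == "SMN" & pb %in% c("DAN", "VAN", "FPN")) |
                    (pb == "SMN" & pa %in% c("DAN", "VAN", "FPN")))
  expect_true(all(em[seg, "beta_age"] < 0))
  expect_true(all(em[seg, "beta_cog"] > 0))
  expect_true(all(em[sub, "beta_age"] < 0)) # age-dominant subcortex
  expect_true(all(em[sub, "beta_cog"] == 0))
  expect_true(all(em[dan, "beta_age"] == 0)) # DAN: cognition-specific
  expect_true(all(em[dan, "beta_cog"] > 0))
  expect_true(all(em[lim, "beta_age"] > 0))
  expect_true(all(em[hub, "beta_age"] > 0))
  expect_true(all(em[hub, "beta_cog"] < 0))
  expect_true(all(em[!(seg | sub | dan | lim | hub), ] == 0))
  expect_lt(cor(em[, "beta_age"], em[, "beta_cog"]), 0)
  # determinism
  expect_identical(em, default_effect_map(a, seed = 7))
})

test_that("two-network atlases put all effects within the first network", {
  a <- make_atlas(c(4, 4), c("A", "B"))
  em <- default_effect_map(a, seed = 1)
  ec <- edge_classes(a)
  between <- ec$pairs$net_a[ec$edge_class] != ec$pairs$net_b[ec$edge_class]
  expect_true(all(em[between, ] == 0))
  within1 <- ec$edge_class == 1
  expect_true(all(em[within1, "beta_age"] < 0))
  expect_error(default_effect_map(make_atlas(5)), "at least 2 networks")
})

test_that("noise-free edges are exact affine functions of standardized age", {
  a <- make_atlas(c(3, 3), c("A", "B"))
  em <- matrix(0, n_edges(6), 2)
  em[4, 1] <- 0.7 # one beta_age edge
  sp <- synthetic_spec(a, n_subjects = 50, edge_effect_map = em,
                       confound_slope = 0, noise_sd = 0, seed = 2)
  co <- simulate_cohort(sp)
  std_age <- scale(co$cohort$age)[, 1]
  expect_equal(co$connectomes[, 4], sp$baseline + 0.7 * std_age,
               tolerance = 1e-12, ignore_attr = TRUE)
  # other edges carry no age effect at all
  expect_equal(sd(co$connectomes[, 1]), 0)
})

test_that("cohort-level age-cognition coupling matches the generating slope", {
  a <- atlas8(3)
  sp <- synthetic_spec(a, n_subjects = 400, age_cog_slope = -0.6, seed = 9)
  co <- simulate_cohort(sp)
  expect_lt(abs(cor(co$cohort$age, co$cohort$gF) - (-0.6)), 0.1)
  # all metrics share the slope
  for (m in sp$metric_names) {
    expect_lt(cor(co$cohort$age, co$cohort[[m]]), -0.3)
  }
  # motion confound is lognormal-ish, positive, mildly age-correlated
  expect_true(all(co$cohort$mean_fd > 0))
  expect_gt(cor(co$cohort$age, co$cohort$mean_fd), 0.05)
})

test_that("a planted cognition edge shows a partial association given age", {
  a <- make_atlas(c(4, 4), c("A", "B"))
  em <- matrix(0, n_edges(8), 2)
  em[10, 2] <- 0.5 # beta_cog only
  sp <- synthetic_spec(a, n_subjects = 400, edge_effect_map = em,
                       noise_sd = 0.5, seed = 4)
  co <- simulate_cohort(sp)
  fit <- summary(lm(co$cohort$gF ~ co$connectomes[, 10] + co$cohort$age))
  expect_gt(fit$coefficients[2, 1], 0)
  expect_lt(fit$coefficients[2, 4], 0.01)
})

test_that("cohort generation is bitwise reproducible from (spec, seed)", {
  sp <- synthetic_spec(atlas8(3), n_subjects = 40, seed = 5)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sp, seed = 6)
  expect_false(identical(c1$connectomes, c3$connectomes))
})

test_that("missingness never removes a subject's last metric", {
  sp <- synthetic_spec(atlas8(3), n_subjects = 200, missing_rate = 0.6,
                       seed = 8)
  co <- simulate_cohort(sp)
  scores <- co$cohort[, sp$metric_names]
  expect_true(any(is.na(scores)))
  expect_true(all(rowSums(!is.na(scores)) >= 1))
})

test_that("doubling edge noise cannot increase expected CV accuracy", {
  a <- atlas8(3)
  r_low <- r_high <- numeric(10)
  for (i in 1:10) {
    for (lvl in c("low", "high")) {
      sp <- synthetic_spec(a, n_subjects = 80,
                           noise_sd = if (lvl == "low") 0.3 else 0.6,
                           seed = 100 + i)
      co <- simulate_cohort(sp)
      cv <- repeated_cv(co$connectomes, co$cohort$age, folds = 5, reps = 1,
                        n_components = 3, seed = 1, keep_fold_maps = FALSE)
      if (lvl == "low") r_low[i] <- cv$summary$r_mean else
        r_high[i] <- cv$summary$r_mean
    }
  }
  expect_gte(mean(r_low), mean(r_high))
})

test_that("simulated time series realize the target connectome", {
  # identity target: off-diagonal correlations shrink toward 0
  z0 <- rep(0, n_edges(4))
  ts <- simulate_timeseries(z0, 5000, seed = 1)
  expect_true(all(abs(cor(t(ts))[lower.tri(diag(4))]) < 0.05))
  # 3-node target with r(1,2) = 0.5 recovered within sampling error
  target <- fisher_z(c(0.5, 0, 0))
  ts2 <- simulate_timeseries(target, 20000, seed = 2)
  r12 <- cor(ts2[1, ], ts2[2, ])
  expect_lt(abs(r12 - 0.5), 0.03)
  # determinism
  expect_identical(simulate_timeseries(target, 100, seed = 3),
                   simulate_timeseries(target, 100, seed = 3))
  # round trip through compute_connectome at large T
  z_rec <- compute_connectome(ts2)
  expect_lt(max(abs(fisher_z_inv(z_rec) - fisher_z_inv(target))), 0.03)
})

test_that("unrepairable targets are rejected", {
  bad <- fisher_z(c(0.9, 0.9, -0.9)) # strongly non-PSD 3-node target
  expect_error(simulate_timeseries(bad, 100, seed = 1), "invalid target")
  expect_error(simulate_timeseries(rep(0, 3), 1, seed = 1), ">= 2 timepoints")
})
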