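test_that("averaging fold maps is the elementwise mean", {
  v <- c(0.2, -0.1, 0.4)
  one <- average_maps(matrix(v, ncol = 1))
  expect_equal(one$values, v)
  expect_equal(one$n_models_averaged, 1L)
  sym <- average_maps(cbind(v, -v))
  expect_equal(sym$values, rep(0, 3))
  three <- average_maps(list(c(1, 0), c(0, 1), c(2, 2)))
  expect_equal(three$values, c(1, 1))
  expect_equal(three$n_models_averaged, 3L)
  expect_error(average_maps(list(c(1, 2), c(1, 2, 3))), "mixed lengths")
  expect_error(average_maps(list()), "empty")
})

test_that("node summary sums incident edge weights", {
  a <- make_atlas(4)
  w <- numeric(n_edges(4))
  w[edge_index(1, 2, 4)] <- 0.6
  w[edge_index(1, 3, 4)] <- -0.2
  w[edge_index(1, 4, 4)] <- 0.2
  ns <- node_summary(w, a)
  expect_equal(ns$level, "node")
  expect_equal(ns$values[1], 0.6) # 0.6 - 0.2 + 0.2
  expect_equal(ns$values[2], 0.6)
  expect_equal(node_summary(numeric(6), a)$values, rep(0, 4))
  # handshake identity on a random map: sum over nodes = 2 x sum over edges
  set.seed(20)
  a10 <- make_atlas(10)
  w10 <- rnorm(n_edges(10))
  expect_equal(sum(node_summary(w10, a10)$values), 2 * sum(w10),
               tolerance = 1e-12)
  # absolute variant
  expect_equal(sum(node_summary(w10, a10, absolute = TRUE)$values),
               2 * sum(abs(w10)), tolerance = 1e-12)
  expect_error(node_summary(w10, a), "shape error")
})

test_that("network summary produces size-normalized sign-split cells", {
  a <- make_atlas(c(2, 2), c("A", "B"))
  # canonical edge order for 4 nodes: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  w <- c(0.6, -0.2, 0.2, -0.1, 0.1, 0.4)
  ns <- network_summary(w, a)
  cells <- ns$cells
  expect_equal(cells$net_a, c("A", "A", "B"))
  expect_equal(cells$net_b, c("A", "B", "B"))
  expect_equal(cells$mean_weight, c(0.6, 0, 0.4))
  expect_equal(cells$pos_norm, c(0.6, 0.075, 0.4))
  expect_equal(cells$neg_norm, c(0, -0.075, 0))
  expect_equal(cells$n_edges, c(1L, 4L, 1L))
  expect_equal(ns$map$values, cells$mean_weight)
  # uniform map: every cell mean is the constant, positives carry it all
  u <- network_summary(rep(0.3, 6), a)
  expect_equal(u$cells$mean_weight, rep(0.3, 3))
  expect_equal(u$cells$pos_norm, rep(0.3, 3))
  expect_equal(u$cells$neg_norm, rep(0, 3))
  # 8-network atlas yields 36 cells
  expect_equal(nrow(network_summary(rnorm(n_edges(24)), atlas8(3))$cells), 36L)
  # a single-node network has an empty within-pair: NA mean, cells aligned
  a1 <- make_atlas(c(2, 1, 2), c("A", "B", "C"))
  ns1 <- network_summary(rep(1, n_edges(5)), a1)
  expect_equal(nrow(ns1$cells), 6L)
  b_within <- ns1$cells$net_a == "B" & ns1$cells$net_b == "B"
  expect_true(is.na(ns1$cells$mean_weight[b_within]))
  expect_equal(ns1$cells$n_edges[b_within], 0L)
  expect_equal(ns1$cells$mean_weight[!b_within], rep(1, 5))
})

test_that("network summary mean cells are linear in the map", {
  set.seed(21)
  a <- atlas8(3)
  w1 <- rnorm(n_edges(24))
  w2 <- rnorm(n_edges(24))
  lhs <- network_summary(2 * w1 - 3 * w2, a)$map$values
  rhs <- 2 * network_summary(w1, a)$map$values -
    3 * network_summary(w2, a)$map$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("overlap handles identity, antisymmetry and incompatible maps", {
  set.seed(22)
  v <- rnorm(100)
  ma <- weight_map(v, "connection")
  self <- overlap(ma, ma, n_perm = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)
  anti <- overlap(ma, weight_map(-v, "connection"), n_perm = 199, seed = 1)
  expect_equal(anti$r, -1)
  expect_equal(anti$p, 1 / 200)
  expect_error(overlap(ma, weight_map(rnorm(10), "node")), "incompatible maps")
  expect_error(overlap(v, rnorm(50)), "lengths differ")
})

test_that("the overlap permutation null is centered at zero", {
  set.seed(23)
  a <- rnorm(400)
  b <- rnorm(400)
  ov <- overlap(a, b, n_perm = 500, seed = 3)
  expect_lt(abs(mean(ov$null_values)), 3 / sqrt(400))
  expect_gt(ov$p, 0.01) # independent maps should not look similar
})

test_that("network aggregation tends to raise the overlap magnitude", {
  # age and cognition models from small cohorts, across seeds: |r| at the
  # network level is on average at least the connection-level |r|
  a <- atlas8(3)
  r_conn <- r_net <- numeric(20)
  for (i in 1:20) {
    sp <- synthetic_spec(a, n_subjects = 80, seed = 300 + i)
    co <- simulate_cohort(sp)
    f_age <- fit_plsr(co$connectomes, co$cohort$age, n_components = 2)
    f_cog <- fit_plsr(co$connectomes, co$cohort$gF, n_components = 2)
    r_conn[i] <- cor(f_age$coefficients, f_cog$coefficients)
    r_net[i] <- cor(network_summary(f_age$coefficients, a)$map$values,
                    network_summary(f_cog$coefficients, a)$map$values)
  }
  expect_true(all(r_conn < 0)) # opposite-signed loadings by construction
  expect_gte(mean(abs(r_net)), mean(abs(r_conn)))
})
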