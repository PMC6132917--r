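complete_adj <- function(n, w) {
  m <- matrix(w, n, n); diag(m) <- 0
  adjacency_matrix(m)
}

star_adj <- function(n, w = 1) {
  m <- matrix(0, n, n); m[1, 2:n] <- w; m[2:n, 1] <- w
  adjacency_matrix(m)
}

test_that("weight-to-length conversion follows the reciprocal rule and policies", {
  w <- matrix(c(0, 0.5, -0.3, 0.5, 0, 0, -0.3, 0, 0), 3)
  adj <- adjacency_matrix(w)
  lz <- to_lengths(adj, "zero")
  expect_equal(lz[1, 2], 2)
  expect_equal(lz[1, 3], Inf)   # negative dropped
  expect_equal(lz[2, 3], Inf)   # zero weight = absent edge
  la <- to_lengths(adj, "abs")
  expect_equal(la[1, 3], 10 / 3)
  expect_equal(diag(lz), rep(0, 3), ignore_attr = TRUE)
  expect_error(to_lengths(adj, "clip"), "arg")
  # all-zero adjacency: every off-diagonal length infinite
  l0 <- to_lengths(complete_adj(4, 0))
  expect_true(all(l0[row(l0) != col(l0)] == Inf))
})

test_that("shortest paths prefer strong indirect routes and count ties", {
  # two strong hops (0.9) beat one weak direct edge (0.1)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 3] <- 0.9; w[1, 3] <- 0.1
  w <- pmax(w, t(w))
  sp <- painnet::shortest_paths(to_lengths(adjacency_matrix(w)))
  expect_equal(sp$distance[1, 3], 2 / 0.9, tolerance = 1e-12)
  expect_equal(sp$counts[1, 3], 1)
  # complete uniform graph: direct edge dominates, one path per pair
  spc <- painnet::shortest_paths(to_lengths(complete_adj(5, 0.5)))
  off <- row(spc$distance) != col(spc$distance)
  expect_true(all(spc$distance[off] == 2))
  expect_true(all(spc$counts[off] == 1))
  # equal-length two-hop ties through distinct intermediates are counted
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 4] <- w4[1, 3] <- w4[3, 4] <- 1
  w4 <- pmax(w4, t(w4))
  sp4 <- painnet::shortest_paths(to_lengths(adjacency_matrix(w4)))
  expect_equal(sp4$counts[1, 4], 2)
})

test_that("distances match a Floyd-Warshall oracle on random graphs", {
  set.seed(31)
  for (k in 1:20) {
    adj <- random_adjacency(sample(4:8, 1), density = 0.6)
    len <- to_lengths(adj)
    sp <- painnet::shortest_paths(len)
    expect_equal(sp$distance, floyd_warshall(len), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("global efficiency matches closed forms", {
  expect_equal(global_efficiency(complete_adj(6, 0.5)), 0.5)
  expect_equal(global_efficiency(complete_adj(4, 0)), 0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 3] <- 0.9; w[1, 3] <- 0.1
  w <- pmax(w, t(w))
  expect_equal(global_efficiency(adjacency_matrix(w)),
               (0.9 + 0.9 + 0.45) / 3)
  expect_error(global_efficiency(adjacency_matrix(matrix(0, 1, 1))),
               "at least 2")
})

test_that("betweenness matches closed forms and the enumeration oracle", {
  expect_equal(unname(betweenness_centrality(complete_adj(5, 0.7))),
               rep(0, 5))
  expect_equal(unname(betweenness_centrality(star_adj(4))), c(3, 0, 0, 0))
  # star with n leaves: center carries every leaf pair once
  expect_equal(unname(betweenness_centrality(star_adj(6)))[1], 5 * 4 / 2)
  set.seed(41)
  for (k in 1:10) {
    adj <- random_adjacency(sample(4:7, 1), density = 0.6)
    expect_equal(unname(betweenness_centrality(adj)), bc_enumeration(adj),
                 tolerance = 1e-12)
  }
  expect_error(betweenness_centrality(complete_adj(2, 1)), "at least 3")
})

test_that("scale covariance: weights x c scales GE by c and leaves BC unchanged", {
  set.seed(51)
  adj <- random_adjacency(7, density = 0.7)
  adj3 <- adjacency_matrix(3 * adj$weights)
  expect_equal(global_efficiency(adj3), 3 * global_efficiency(adj),
               tolerance = 1e-12)
  expect_equal(betweenness_centrality(adj3), betweenness_centrality(adj),
               tolerance = 1e-12)
})

test_that("GE is monotone non-decreasing under a single weight increase", {
  set.seed(61)
  for (k in 1:10) {
    adj <- random_adjacency(6, density = 0.5)
    ge0 <- global_efficiency(adj)
    w <- adj$weights
    ij <- sample(6, 2)
    w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- w[ij[1], ij[2]] + runif(1, 0.05, 0.5)
    expect_gte(global_efficiency(adjacency_matrix(w)), ge0 - 1e-12)
  }
})

test_that("BC z-scoring has the z identities and a zero-spread rule", {
  set.seed(71)
  bc <- runif(20)
  z <- zscore_bc(bc)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)  # population sd
  expect_equal(zscore_bc(rep(2, 5)), rep(0, 5), ignore_attr = TRUE)
  expect_equal(zscore_bc(c(0, 3, 0, 0)),
               c(-0.5773503, 1.7320508, -0.5773503, -0.5773503),
               tolerance = 1e-6, ignore_attr = TRUE)
  zs <- zscore_bc(bc, sd_type = "sample")
  expect_equal(sd(zs), 1, tolerance = 1e-12)
})

test_that("topology summary composes GE and subnetwork-averaged z-BC correctly", {
  set.seed(81)
  n <- 12
  adj <- random_adjacency(n, density = 0.8)
  wb <- node_set("whole_brain", 1:n, n)
  sub <- node_set("pain", c(2, 5, 7, 9), n)
  sm <- summarize_topology(adj, list(sub))
  expect_equal(sm$ge_whole_brain, global_efficiency(adj))
  expect_equal(sm$ge_pain, global_efficiency(induced_subgraph(adj, sub)))
  zbc <- zscore_bc(betweenness_centrality(adj))
  expect_equal(sm$bc_pain, mean(zbc[sub$indices]))
  # whole-brain subnetwork: mean z-BC identically 0
  sm_wb <- summarize_topology(adj, list(wb))
  expect_equal(sm_wb$bc_whole_brain, 0, tolerance = 1e-12)

  # block-diagonal adjacency: dense uniform pain block of weight w
  w <- 0.6
  m <- matrix(0, n, n)
  blk <- sub$indices
  m[blk, blk] <- w; diag(m) <- 0
  smb <- summarize_topology(adjacency_matrix(m), list(sub))
  expect_equal(smb$ge_pain, w)

  # permutation invariance of every summary value
  perm <- sample(n)
  adj_p <- adjacency_matrix(adj$weights[perm, perm])
  sub_p <- node_set("pain", match(sub$indices, perm), n)
  sm_p <- summarize_topology(adj_p, list(sub_p))
  for (col in c("ge_whole_brain", "ge_pain", "bc_pain"))
    expect_equal(sm_p[[col]], sm[[col]], tolerance = 1e-10)
})

test_that("restricted subnetwork GE uses whole-brain paths", {
  # pain nodes connected only through an outside relay: induced GE is 0,
  # restricted GE sees the two-hop whole-brain paths
  n <- 5
  m <- matrix(0, n, n)
  m[1, 5] <- m[2, 5] <- m[3, 5] <- 1
  m <- pmax(m, t(m))
  adj <- adjacency_matrix(m)
  sub <- node_set("pain", 1:3, n)
  ind <- summarize_topology(adj, list(sub), subnetwork_ge = "induced")
  res <- summarize_topology(adj, list(sub), subnetwork_ge = "restricted")
  expect_equal(ind$ge_pain, 0)
  expect_equal(res$ge_pain, 0.5)  # every pair at distance 2 via the relay
})

test_that("planted pain-block coupling raises expected pain-network GE", {
  ge_at <- function(r_pain, seeds) {
    vapply(seeds, function(s) {
      d <- tiny_design(seed = s, pain_r = c(patient = r_pain, control = 0.1),
                       noise_sd = 0, motion_spike_prob = 0)
      sub <- simulate_subject(d, "patient", seed = s)
      conn <- build_adjacency(sub$time_series, sub$motion, drop_volumes = 0)
      global_efficiency(induced_subgraph(conn$adjacency,
                                         node_set("p", 1:4, 12)))
    }, numeric(1))
  }
  seeds <- 1:12
  lo <- mean(ge_at(0.2, seeds))
  mid <- mean(ge_at(0.45, seeds))
  hi <- mean(ge_at(0.7, seeds))
  expect_lt(lo, mid)
  expect_lt(mid, hi)
})
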