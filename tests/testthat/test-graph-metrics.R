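test_that("degree and strength satisfy the handshake lemma", {
  tri <- unit_triangle()
  ds <- degree_strength(tri)
  expect_equal(ds$degree, rep(2L, 3))
  expect_equal(ds$strength, rep(2, 3))

  w <- wmat(4, cbind(c(1, 1), c(2, 3), 1)) # node 4 isolated
  ds2 <- degree_strength(tnet(w))
  expect_equal(ds2$degree[4], 0L)
  expect_equal(ds2$strength[4], 0)

  set.seed(1)
  ts <- subject_timeseries(matrix(rnorm(60 * 100), 60, 100))
  net <- proportional_threshold(correlation_matrix(ts), 0.16)
  ds3 <- degree_strength(net)
  expect_equal(sum(ds3$degree), 2L * 283L) # mean degree 2E/N = 9.43
})

test_that("Onnela clustering and weighted transitivity match hand values", {
  tri <- unit_triangle()
  ct <- clustering_transitivity(tri)
  expect_equal(ct$cc, rep(1, 3))
  expect_equal(ct$transitivity, 1)

  star <- star_graph(5)
  ct2 <- clustering_transitivity(star)
  expect_equal(ct2$cc, rep(0, 6))
  expect_equal(ct2$transitivity, 0)

  # ab = 1, ac = 1, bc = 0.5, cd = 1: CC(a) = (1 * 1 * 0.5)^(1/3)
  w <- wmat(4, rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 0.5), c(3, 4, 1)))
  cc <- clustering_transitivity(tnet(w))$cc
  expect_equal(cc[1], 0.5^(1 / 3), tolerance = 1e-10)

  expect_error(clustering_transitivity(tnet(matrix(c(0, -1, -1, 0), 2))),
               "nonnegative")
})

test_that("path metrics match hand computation and state conventions", {
  pm <- path_metrics(path_abc()) # distances 1, 1, 2
  expect_equal(pm$cpl, 4 / 3, tolerance = 1e-10)
  expect_equal(pm$global_efficiency, mean(c(1, 1, 0.5)), tolerance = 1e-10)

  complete4 <- tnet(wmat(4, cbind(t(combn(1:4, 2)), 1)))
  pmc <- path_metrics(complete4)
  expect_equal(pmc$cpl, 1)
  expect_equal(pmc$global_efficiency, 1)

  # two components: infinite pairs out of CPL, zero efficiency contribution
  w <- wmat(4, rbind(c(1, 2, 1), c(3, 4, 1)))
  pm2 <- path_metrics(tnet(w))
  expect_equal(pm2$cpl, 1)
  expect_equal(pm2$global_efficiency, 2 / 6)
  expect_equal(pm2$n_disconnected_pairs, 4L)

  empty <- tnet(matrix(0, 3, 3))
  expect_true(is.na(path_metrics(empty)$cpl))
})

test_that("weighted CPL and efficiency agree with a brute-force path oracle", {
  set.seed(21)
  w <- wmat(6, cbind(t(combn(1:6, 2)), 0))
  pairs <- t(combn(1:6, 2))
  keep <- sample(nrow(pairs), 9)
  for (r in keep) {
    w[pairs[r, 1], pairs[r, 2]] <- w[pairs[r, 2], pairs[r, 1]] <- runif(1, 0.2, 1)
  }
  oracle <- brute_force_efficiency(w)
  pm <- path_metrics(tnet(w))
  expect_equal(pm$cpl, oracle$cpl, tolerance = 1e-10)
  expect_equal(pm$global_efficiency, oracle$efficiency, tolerance = 1e-10)
})

test_that("local efficiency matches trivial cases and a brute-force oracle", {
  expect_equal(local_efficiency(unit_triangle()), rep(1, 3))
  expect_equal(local_efficiency(star_graph(4))[1], 0)

  set.seed(13)
  w <- wmat(5, rbind(c(1, 2, 1), c(1, 3, 0.8), c(1, 4, 0.6), c(2, 3, 0.9),
                     c(3, 4, 0.4), c(4, 5, 1), c(1, 5, 0.7)))
  le <- local_efficiency(tnet(w))
  wn <- w / max(w)
  for (i in 1:5) {
    nb <- which(wn[i, ] > 0)
    expected <- if (length(nb) < 2) 0 else
      brute_force_efficiency(wn[nb, nb, drop = FALSE])$efficiency
    expect_equal(le[i], expected, tolerance = 1e-10)
  }
})

test_that("assortativity reproduces closed forms and flags degeneracy", {
  expect_equal(assortativity_index(star_graph(5), "degree"), -1,
               tolerance = 1e-12)

  two_tri <- tnet(wmat(6, cbind(rbind(t(combn(1:3, 2)), t(combn(4:6, 2))), 1)))
  expect_warning(r <- assortativity_index(two_tri, "degree"), "zero variance")
  expect_true(is.na(r))

  # two joined hubs with pendant leaves: disassortative
  w <- wmat(8, rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                     c(2, 5, 1), c(2, 6, 1), c(2, 7, 1), c(1, 8, 1)))
  expect_lt(assortativity_index(tnet(w), "degree"), 0)

  # oracle: direct edge-list correlation on a random weighted graph
  net <- er_weighted(20, 40, seed = 5)
  ds <- degree_strength(net)
  pairs <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  x <- c(ds$strength[pairs[, 1]], ds$strength[pairs[, 2]])
  y <- c(ds$strength[pairs[, 2]], ds$strength[pairs[, 1]])
  expect_equal(assortativity_index(net, "strength"), cor(x, y),
               tolerance = 1e-12)
})

test_that("participation coefficient follows the within-module degree formula", {
  # all edges within own module
  two_tri <- tnet(wmat(6, cbind(rbind(t(combn(1:3, 2)), t(combn(4:6, 2))), 1)))
  expect_equal(participation_coefficient(two_tri, c(1, 1, 1, 2, 2, 2)),
               rep(0, 6))

  # node 1 splits edges equally across 2 modules
  w <- wmat(3, rbind(c(1, 2, 1), c(1, 3, 1)))
  p <- participation_coefficient(tnet(w), c(1, 1, 2))
  expect_equal(p[1], 0.5)

  # equal thirds across 3 modules
  w3 <- wmat(4, rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
  p3 <- participation_coefficient(tnet(w3), c(1, 1, 2, 3))
  expect_equal(p3[1], 1 - 3 * (1 / 3)^2)

  expect_equal(participation_coefficient(tnet(matrix(0, 3, 3)), c(1, 1, 2)),
               rep(0, 3))
  expect_error(participation_coefficient(two_tri, c(1, 2)), "length")
})

test_that("small-world indices behave as the canonical benchmarks dictate", {
  # self-referenced network: gamma = lambda = SWC = 1
  net <- er_net(30, 100, seed = 2)
  sw_self <- small_world(net, list(net))
  expect_equal(sw_self$gamma, 1)
  expect_equal(sw_self$lambda, 1)
  expect_equal(sw_self$swc, 1)

  # ER graphs vs matched ensembles: SWC close to 1 on average
  swcs <- vapply(1:10, function(i) {
    n <- er_net(40, 160, seed = 100 + i)
    small_world(n, null_ensemble_net(n, m = 5, seed = i))$swc
  }, numeric(1))
  expect_gt(mean(swcs), 0.85)
  expect_lt(mean(swcs), 1.15)

  # Watts-Strogatz ring: SWC > 1
  set.seed(9)
  ws <- igraph::sample_smallworld(1, 60, 5, 0.1)
  net_ws <- tnet(igraph::as_adjacency_matrix(ws, sparse = FALSE) * 1)
  sw <- small_world(net_ws, null_ensemble_net(net_ws, m = 10, seed = 4),
                    lattice_reference(net_ws, seed = 8))
  expect_gt(sw$swc, 1)
  expect_true(is.finite(sw$swm))
})

test_that("rich-club curve matches exhaustive evaluation on toy graphs", {
  complete5 <- tnet(wmat(5, cbind(t(combn(1:5, 2)), 1)))
  rc <- rich_club(complete5, list(complete5))
  expect_true(all(rc$phi[!is.na(rc$phi)] == 1))

  star <- star_graph(5)
  rc_star <- rich_club(star, list(star))
  expect_true(all(is.na(rc_star$phi[rc_star$k >= 1])))

  # 6-node toy: strongly weighted 3-node core
  w <- wmat(6, rbind(c(1, 2, 0.9), c(1, 3, 0.8), c(2, 3, 0.7),
                     c(1, 4, 0.3), c(2, 5, 0.2), c(3, 6, 0.1),
                     c(4, 5, 0.15)))
  net <- tnet(w)
  rc2 <- rich_club(net, list(net))
  # club at k = 2: nodes with degree > 2 = {1, 2, 3}; E = 3, W = 2.4
  all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  expect_equal(rc2$phi[rc2$k == 2], (0.9 + 0.8 + 0.7) / sum(all_w[1:3]),
               tolerance = 1e-12)
  expect_true(all(rc2$phi >= 0 & rc2$phi <= 1, na.rm = TRUE))
})

test_that("normalized rich club of weighted ER graphs sits near 1 at small k", {
  vals <- c()
  for (i in 1:5) {
    net <- er_weighted(40, 160, seed = 200 + i)
    rc <- rich_club(net, null_ensemble_net(net, m = 5, seed = i))
    vals <- c(vals, rc$phi_norm[rc$k <= 5])
  }
  vals <- vals[!is.na(vals)]
  expect_gt(mean(vals >= 0.85 & vals <= 1.15), 0.9)
})

test_that("metrics are invariant under node relabeling", {
  net <- er_weighted(15, 40, seed = 33)
  set.seed(34)
  perm <- sample(15)
  w2 <- net$weights[perm, perm]
  net2 <- tnet(w2)
  expect_equal(sort(degree_strength(net2)$strength),
               sort(degree_strength(net)$strength), tolerance = 1e-12)
  expect_equal(clustering_transitivity(net2)$transitivity,
               clustering_transitivity(net)$transitivity, tolerance = 1e-12)
  expect_equal(path_metrics(net2)$cpl, path_metrics(net)$cpl,
               tolerance = 1e-12)
  expect_equal(sort(clustering_transitivity(net2)$cc),
               sort(clustering_transitivity(net)$cc), tolerance = 1e-12)
})

test_that("uniform-weight graphs reduce to their binary counterparts", {
  net <- er_net(20, 60, seed = 44) # unit weights
  ct <- clustering_transitivity(net)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected")
  expect_equal(ct$transitivity, igraph::transitivity(g, type = "global"),
               tolerance = 1e-10)
  cc_ig <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  expect_equal(ct$cc, cc_ig, tolerance = 1e-10)
})
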