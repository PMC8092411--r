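test_that("stationary distribution follows degree weighting", {
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::E(g2)$weight <- 1
  expect_equal(unname(stationary_distribution(g2)), c(0.5, 0.5))

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::E(star)$weight <- 1
  expect_equal(unname(stationary_distribution(star)), c(1/2, 1/6, 1/6, 1/6))

  set.seed(1)
  g <- random_weighted_graph(12)
  expect_equal(sum(stationary_distribution(g)), 1)
  gd <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  igraph::E(gd)$weight <- 1
  expect_error(stationary_distribution(gd), "connected")
})

test_that("stability of the trivial partition is zero at every Markov time", {
  set.seed(2)
  for (i in 1:5) {
    g <- random_weighted_graph(sample(4:12, 1))
    n <- igraph::vcount(g)
    for (t in c(0.1, 1, 7)) {
      expect_equal(partition_stability(g, rep(1, n), t, "linearized"), 0,
                   tolerance = 1e-12)
      expect_equal(partition_stability(g, rep(1, n), t, "exact"), 0,
                   tolerance = 1e-10)
    }
  }
})

test_that("exact stability at t = 0 equals one minus the participation sum", {
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::E(g2)$weight <- 1
  expect_equal(partition_stability(g2, c(1, 2), 0, "exact"), 0.5,
               tolerance = 1e-12)
})

test_that("linearised stability at t = 1 is Newman modularity", {
  # barbell of two triangles: hand value 2 * (3/7 - (7/14)^2) = 5/14
  bb <- barbell_graph()
  r <- partition_stability(bb, c(1, 1, 1, 2, 2, 2), 1, "linearized")
  expect_equal(r, 5 / 14, tolerance = 1e-14)
  expect_equal(r, 0.357142857, tolerance = 1e-9)

  set.seed(3)
  for (i in 1:10) {
    g <- random_weighted_graph(sample(5:30, 1))
    memb <- sample(1:4, igraph::vcount(g), replace = TRUE)
    expect_equal(partition_stability(g, memb, 1, "linearized"),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("exact and linearised stability agree to first order in t", {
  set.seed(4)
  g <- random_weighted_graph(12)
  memb <- sample(1:3, 12, replace = TRUE)
  d1 <- abs(partition_stability(g, memb, 1e-3, "exact") -
              partition_stability(g, memb, 1e-3, "linearized"))
  d2 <- abs(partition_stability(g, memb, 1e-2, "exact") -
              partition_stability(g, memb, 1e-2, "linearized"))
  # O(t^2) scaling: a 10x larger t gives ~100x the discrepancy
  expect_gt(d2 / d1, 30)
  expect_lt(d2 / d1, 300)
})

test_that("the optimiser recovers planted blocks and is seed-deterministic", {
  # two 4-cliques bridged by a floored edge
  el <- t(combn(1:4, 2))
  el <- rbind(el, t(combn(5:8, 2)), c(4, 5))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- c(rep(1, 12), 1e-6)

  p <- optimize_partition(g, 1, n_restarts = 20, seed = 3)
  expect_equal(length(unique(p)), 2)
  expect_equal(unname(p[1:4]), rep(p[[1]], 4))
  expect_equal(unname(p[5:8]), rep(p[[5]], 4))
  bf <- brute_force_optimum(g, 1)
  expect_equal(attr(p, "stability"), attr(bf, "stability"), tolerance = 1e-12)

  # more restarts never lower the attained stability
  r1 <- attr(optimize_partition(g, 1, n_restarts = 1, seed = 7), "stability")
  r50 <- attr(optimize_partition(g, 1, n_restarts = 50, seed = 7), "stability")
  expect_gte(r50, r1)

  expect_identical(optimize_partition(g, 1, 10, seed = 5),
                   optimize_partition(g, 1, 10, seed = 5))
})

test_that("variation of information is a metric with known exact values", {
  p <- c(1, 2, 3, 4); q <- c(1, 1, 1, 1)
  expect_equal(variation_of_information(p, p), 0)
  expect_equal(variation_of_information(p, q), log(4), tolerance = 1e-12)
  set.seed(6)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:4, 12, replace = TRUE)
  expect_equal(variation_of_information(a, b), variation_of_information(b, a))
  expect_lte(variation_of_information(a, b), log(12))
  expect_error(variation_of_information(1:3, 1:4), "different node sets")
})

test_that("the Markov-time scan reports finite stabilities and robust restarts", {
  g <- two_clique_graph()
  scan <- scan_markov_times(g, t_grid = c(0.5, 1, 2), n_restarts = 10, seed = 2)
  expect_length(scan$r, 3)
  expect_true(all(is.finite(scan$r)))
  # the two-clique optimum is unambiguous: restarts agree exactly
  expect_equal(scan$mean_vi[2], 0)
  expect_equal(scan$n_clusters[2], 2)
  expect_error(scan_markov_times(g, t_grid = numeric(0)), "empty")
})

test_that("cluster counts coarsen along the Markov-time grid", {
  set.seed(9)
  # planted 3-block graph
  blocks <- lapply(0:2, function(b) t(combn(b * 4 + 1:4, 2)))
  el <- do.call(rbind, c(blocks, list(rbind(c(4, 5), c(8, 9)))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- c(rep(1, 18), 0.05, 0.05)
  scan <- scan_markov_times(g, t_grid = logspace(0.01, 100, 12),
                            n_restarts = 10, seed = 4)
  violations <- sum(diff(scan$n_clusters) > 0)
  expect_lte(violations, 1)
})

test_that("plateau selection honours robustness and the larger-t tie rule", {
  mk_scan <- function(t, nc, vi, partitions, r = rep(0.5, length(t))) {
    structure(list(t = t, partitions = partitions, r = r, n_clusters = nc,
                   mean_vi = vi, vi_consecutive = rep(0, length(t)),
                   n_nodes = 10), class = "stability_scan")
  }
  parts <- lapply(1:6, function(i) rep(i, 10))

  # single long zero-VI plateau at c = 2
  scan1 <- mk_scan(1:6, c(5, 2, 2, 2, 2, 3), rep(0, 6), parts)
  sel1 <- select_robust_partition(scan1, vi_max = 0.1)
  expect_equal(sel1, parts[[4]], ignore_attr = TRUE)  # centre of 2:5, later mid
  expect_false(attr(sel1, "flagged"))

  # two equal-length plateaus: the larger-t one wins
  scan2 <- mk_scan(1:6, c(4, 4, 3, 3, 2, 2), rep(0, 6), parts)
  sel2 <- select_robust_partition(scan2, vi_max = 0.1)
  expect_equal(attr(sel2, "t"), 6)

  # high restart VI breaks plateaus; nothing robust -> flagged max-r fallback
  scan3 <- mk_scan(1:6, rep(2, 6), rep(1, 6), parts, r = c(1:6) / 10)
  sel3 <- select_robust_partition(scan3, vi_max = 0.1)
  expect_true(attr(sel3, "flagged"))
  expect_equal(sel3, parts[[6]], ignore_attr = TRUE)
})

test_that("brute force enumeration matches hand-derived optima", {
  tri <- igraph::make_full_graph(3)
  igraph::E(tri)$weight <- 1
  bf <- brute_force_optimum(tri, 1)
  # no split of a triangle has positive modularity: all-in-one is optimal
  expect_equal(attr(bf, "stability"), 0, tolerance = 1e-14)

  g <- two_clique_graph()
  bf2 <- brute_force_optimum(g, 1)
  expect_equal(unname(bf2[1:3]), rep(bf2[[1]], 3))
  expect_equal(unname(bf2[4:6]), rep(bf2[[4]], 3))
  expect_equal(length(unique(bf2)), 2)

  g1 <- igraph::make_graph(integer(0), n = 1)
  expect_error(brute_force_optimum(igraph::make_full_graph(11), 1), "capped")
})

test_that("cluster mean profiles are plain arithmetic summaries", {
  p <- rbind(f1 = c(0, 2, 4), f2 = c(0, 2, 4), f3 = c(4, 2, 0), f4 = c(4, 2, 0))
  tab <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(feature_id = rownames(p), day = j, log2FC = p[, j],
               t = 0, p = 0, q = 0, call = "up")
  }))
  prof <- standardize_profiles(tab)
  part <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(p))
  cm <- cluster_mean_profiles(part, prof)
  expect_equal(unname(cm$sizes), c(2L, 2L))
  z <- c(-1.2247449, 0, 1.2247449)
  expect_equal(unname(cm$mean["cluster1", ]), z, tolerance = 1e-6)
  expect_equal(unname(cm$mean["cluster2", ]), rev(z), tolerance = 1e-6)
  expect_equal(unname(cm$se), matrix(0, 2, 3), tolerance = 1e-12)

  # singleton clusters: means equal the profiles themselves
  part4 <- stats::setNames(1:4, rownames(p))
  cm4 <- cluster_mean_profiles(part4, prof)
  expect_equal(unname(cm4$mean), unname(prof$profiles), tolerance = 1e-12)
  expect_error(cluster_mean_profiles(part[1:2], prof), "cover")
})
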