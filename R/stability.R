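#' Stationary distribution of the random walk on a weighted graph
#'
#' @param graph a connected, undirected, weighted igraph object.
#' @return numeric vector `pi_i = d_i / sum(d)` (named by vertex), summing
#'   to 1.
#' @export
stationary_distribution <- function(graph) {
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  d <- igraph::strength(graph)
  d / sum(d)
}

# shared pieces: dense adjacency, strengths, total ordered-pair weight
graph_arrays <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = TRUE))
  d <- rowSums(A)
  list(A = A, d = d, w2 = sum(d), pi = d / sum(d))
}

# r_lin for a membership vector given precomputed arrays
stability_linearized <- function(arr, membership, t) {
  cl <- as.integer(factor(membership))
  M <- rowsum(arr$A, cl)
  B <- rowsum(t(M), cl)
  in_total <- sum(diag(as.matrix(B)))
  pi_c <- rowsum(arr$pi, cl)
  (1 - t) + t * in_total / arr$w2 - sum(pi_c^2)
}

#' Markov stability of a partition
#'
#' Computes the stability `r(t, H)` of a hard partition `H` of a connected
#' weighted graph at Markov time `t`. The exact form is
#' `trace(H' (Pi expm(-t L) - pi pi') H)` with `L = I - D^{-1} A` the
#' random-walk Laplacian, `Pi = diag(pi)` and `pi` the stationary
#' distribution; the linearised form is
#' `(1 - t) + t * sum_c(in_c) / w2 - sum_c(pi_c^2)`, which equals
#' Newman-Girvan modularity at `t = 1`. The matrix exponential is obtained
#' by dense eigendecomposition of the symmetrised Laplacian, so exact mode
#' is capped at `n_exact` nodes.
#'
#' @param graph connected, undirected, weighted igraph object.
#' @param partition integer (or factor) membership vector over the vertices.
#' @param t Markov time (>= 0).
#' @param mode `"exact"` or `"linearized"`.
#' @param n_exact node cap for exact mode.
#' @return the stability value (scalar).
#' @export
partition_stability <- function(graph, partition, t,
                                mode = c("linearized", "exact"),
                                n_exact = 2000) {
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  if (length(partition) != n) stop("partition length must match vertex count")
  arr <- graph_arrays(graph)
  if (mode == "linearized") {
    return(stability_linearized(arr, partition, t))
  }
  if (n > n_exact) stop("exact mode capped at ", n_exact, " nodes")
  ds <- sqrt(arr$d)
  Lsym <- diag(n) - arr$A / outer(ds, ds)
  eig <- eigen(Lsym, symmetric = TRUE)
  Et <- eig$vectors %*% (exp(-t * eig$values) * t(eig$vectors))
  P <- (outer(ds, ds) * Et) / arr$w2        # Pi expm(-tL), symmetric
  R <- P - outer(arr$pi, arr$pi)
  cl <- as.integer(factor(partition))
  sum(diag(as.matrix(rowsum(t(rowsum(R, cl)), cl))))
}

#' Optimise Markov stability at one Markov time
#'
#' Louvain-style greedy maximisation of the linearised stability objective,
#' restarted from `n_restarts` random node orders; the best restart is
#' returned. Deterministic for a fixed seed (each restart derives its own
#' child seed).
#'
#' @param graph connected, undirected, weighted igraph object.
#' @param t Markov time.
#' @param n_restarts number of random-order restarts (>= 1).
#' @param seed integer seed.
#' @param keep_restarts if `TRUE`, all restart partitions are attached as
#'   attribute `"restarts"` (used for robustness estimation).
#' @return integer membership vector (1-based contiguous labels, named by
#'   vertex) with attribute `"stability"`.
#' @export
optimize_partition <- function(graph, t, n_restarts = 50, seed = 1,
                               keep_restarts = FALSE) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  arr <- graph_arrays(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  n <- igraph::vcount(graph)
  best <- NULL
  best_r <- -Inf
  restarts <- vector("list", n_restarts)
  run_one <- function(seed_k, init) {
    m <- .louvain_cpp(n, as.integer(el[, 1] - 1L), as.integer(el[, 2] - 1L),
                      w, arr$pi, arr$w2, t, seed_k, init)
    relabel_partition(m + 1L)
  }
  for (k in seq_len(n_restarts)) {
    # each restart tries a singleton-grown and a random-coarse-seeded run
    # and keeps the better: the second escapes local optima that need
    # coordinated multi-node moves, the first bounds the quality
    m1 <- run_one(child_seed(seed, 2 * k), 0L)
    m2 <- run_one(child_seed(seed, 2 * k + 1), max(2L, ceiling(n / 3)))
    r1 <- stability_linearized(arr, m1, t)
    r2 <- stability_linearized(arr, m2, t)
    memb <- if (r2 > r1 + 1e-13) m2 else m1
    restarts[[k]] <- memb
    r <- max(r1, r2)
    if (r > best_r + 1e-13) { best_r <- r; best <- memb }
  }
  names(best) <- igraph::V(graph)$name
  attr(best, "stability") <- best_r
  if (keep_restarts) attr(best, "restarts") <- restarts
  best
}

# relabel memberships to contiguous 1-based labels in order of appearance
relabel_partition <- function(m) match(m, unique(m))

#' Variation of information between two partitions
#'
#' `VI = H(P) + H(Q) - 2 I(P; Q)` in nats, a metric on partitions of the
#' same node set: 0 iff identical, at most `log(n)`.
#'
#' @param P,Q membership vectors over the same nodes (aligned by name when
#'   both are named).
#' @return VI in nats.
#' @export
variation_of_information <- function(P, Q) {
  if (length(P) != length(Q)) stop("partitions cover different node sets")
  if (!is.null(names(P)) && !is.null(names(Q))) {
    if (!setequal(names(P), names(Q))) stop("partitions cover different node sets")
    Q <- Q[names(P)]
  }
  n <- length(P)
  pi_ <- as.integer(factor(P))
  qi <- as.integer(factor(Q))
  joint <- tabulate(pi_ + (qi - 1L) * max(pi_), max(pi_) * max(qi)) / n
  pp <- tabulate(pi_) / n
  qq <- tabulate(qi) / n
  ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  hp <- ent(pp); hq <- ent(qq); hpq <- ent(joint)
  max(2 * hpq - hp - hq, 0)
}

#' Scan Markov times and record partition robustness
#'
#' Runs [optimize_partition()] on a (log-spaced) grid of Markov times and
#' records, per time: the best partition, its stability, the number of
#' clusters, and the mean pairwise VI across the optimiser restarts (the
#' within-time robustness signal). The VI between consecutive best
#' partitions is also recorded.
#'
#' @inheritParams optimize_partition
#' @param t_grid strictly increasing Markov-time grid.
#' @return object of class `stability_scan`: list with `t`, `partitions`,
#'   `r`, `n_clusters`, `mean_vi`, `vi_consecutive`, `n_nodes`.
#' @export
scan_markov_times <- function(graph, t_grid = logspace(1e-2, 1e2, 50),
                              n_restarts = 50, seed = 1) {
  if (length(t_grid) == 0) stop("empty Markov-time grid")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  partitions <- vector("list", length(t_grid))
  r <- n_clusters <- mean_vi <- numeric(length(t_grid))
  for (i in seq_along(t_grid)) {
    p <- optimize_partition(graph, t_grid[i], n_restarts = n_restarts,
                            seed = child_seed(seed, i), keep_restarts = TRUE)
    restarts <- attr(p, "restarts")
    attr(p, "restarts") <- NULL
    partitions[[i]] <- p
    r[i] <- attr(p, "stability")
    n_clusters[i] <- length(unique(p))
    mean_vi[i] <- mean_pairwise_vi(restarts)
  }
  vi_consec <- c(NA_real_, vapply(seq_along(t_grid)[-1], function(i) {
    variation_of_information(unname(partitions[[i - 1]]), unname(partitions[[i]]))
  }, numeric(1)))
  structure(list(t = t_grid, partitions = partitions, r = r,
                 n_clusters = n_clusters, mean_vi = mean_vi,
                 vi_consecutive = vi_consec,
                 n_nodes = igraph::vcount(graph)),
            class = "stability_scan")
}

# mean pairwise VI over restart partitions, collapsing duplicates first
mean_pairwise_vi <- function(restarts) {
  R <- length(restarts)
  if (R < 2) return(0)
  keys <- vapply(restarts, function(m) paste(relabel_partition(m), collapse = ","),
                 character(1))
  uk <- unique(keys)
  if (length(uk) == 1) return(0)
  counts <- as.numeric(table(factor(keys, levels = uk)))
  reps <- restarts[match(uk, keys)]
  total <- 0
  for (a in seq_along(uk)[-1]) {
    for (b in seq_len(a - 1)) {
      total <- total + counts[a] * counts[b] *
        variation_of_information(reps[[a]], reps[[b]])
    }
  }
  total / (R * (R - 1) / 2)
}

#' @export
print.stability_scan <- function(x, ...) {
  cat(sprintf("stability_scan: %d Markov times in [%.3g, %.3g], %d nodes\n",
              length(x$t), min(x$t), max(x$t), x$n_nodes))
  cat(sprintf("cluster counts: %s\n",
              paste(rle(x$n_clusters)$values, collapse = " -> ")))
  invisible(x)
}

#' @export
as.data.frame.stability_scan <- function(x, ...) {
  data.frame(t = x$t, r = x$r, n_clusters = x$n_clusters,
             mean_vi = x$mean_vi, vi_consecutive = x$vi_consecutive)
}

#' Select the robust partition from a stability scan
#'
#' Picks the partition at the centre of the longest contiguous Markov-time
#' plateau on which (a) the cluster count is constant and (b) the mean
#' restart VI is at most `vi_max`. Ties are broken toward larger Markov
#' time, as is the centre of an even-length plateau. When no grid point is
#' robust the globally best-stability partition is returned with attribute
#' `"flagged" = TRUE`.
#'
#' @param scan a `stability_scan`.
#' @param vi_max robustness threshold; default `0.05 * log(n)`.
#' @return membership vector with attributes `"t"` (selected Markov time),
#'   `"plateau"` (index range) and `"flagged"`.
#' @export
select_robust_partition <- function(scan, vi_max = 0.05 * log(scan$n_nodes)) {
  stopifnot(inherits(scan, "stability_scan"))
  ok <- scan$mean_vi <= vi_max
  # maximal runs of constant cluster count among robust points
  run_id <- cumsum(c(TRUE, diff(scan$n_clusters) != 0 | diff(ok) != 0))
  best_run <- NULL
  best_len <- 0
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (!ok[idx[1]]) next
    if (length(idx) >= best_len) {  # >= : ties go to larger t (later runs)
      best_len <- length(idx)
      best_run <- idx
    }
  }
  if (is.null(best_run)) {
    i <- which.max(scan$r)
    p <- scan$partitions[[i]]
    attr(p, "t") <- scan$t[i]
    attr(p, "plateau") <- NA
    attr(p, "flagged") <- TRUE
    return(p)
  }
  centre <- best_run[1] + ceiling((length(best_run) - 1) / 2)
  p <- scan$partitions[[centre]]
  attr(p, "t") <- scan$t[centre]
  attr(p, "plateau") <- range(best_run)
  attr(p, "flagged") <- FALSE
  p
}

#' Exhaustive stability optimum (test oracle)
#'
#' Enumerates every set partition of the vertices (restricted-growth
#' strings) and returns the one maximising linearised stability. Only
#' feasible for tiny graphs.
#'
#' @param graph connected, undirected, weighted igraph with at most 10
#'   vertices.
#' @param t Markov time.
#' @return membership vector with attribute `"stability"`.
#' @export
brute_force_optimum <- function(graph, t) {
  n <- igraph::vcount(graph)
  if (n > 10) stop("brute force capped at 10 nodes")
  arr <- graph_arrays(graph)
  best <- rep(1L, n)
  best_r <- stability_linearized(arr, best, t)
  rgs <- integer(n)
  recurse <- function(pos, maxlab) {
    if (pos > n) {
      r <- stability_linearized(arr, rgs, t)
      if (r > best_r + 1e-15) { best_r <<- r; best <<- rgs }
      return(invisible(NULL))
    }
    for (lab in seq_len(maxlab + 1L)) {
      rgs[pos] <<- lab
      recurse(pos + 1L, max(maxlab, lab))
    }
  }
  if (n >= 1) { rgs[1] <- 1L; recurse(2L, 1L) }
  names(best) <- igraph::V(graph)$name
  attr(best, "stability") <- best_r
  best
}

#' Per-cluster mean temporal profiles
#'
#' Arithmetic mean day course (and standard error) per cluster of a
#' partition over standardised profiles, with cluster sizes.
#'
#' @param partition membership vector named by feature ID.
#' @param profiles a `temporal_profiles` object covering those features.
#' @return list with `mean` (cluster x day), `se`, `sizes`.
#' @export
cluster_mean_profiles <- function(partition, profiles) {
  stopifnot(inherits(profiles, "temporal_profiles"))
  feats <- rownames(profiles$profiles)
  if (!all(feats %in% names(partition))) {
    stop("partition does not cover all profile features")
  }
  cl <- partition[feats]
  if (any(table(cl) == 0)) stop("empty cluster")
  p <- profiles$profiles
  k <- sort(unique(cl))
  mean_m <- t(vapply(k, function(c) colMeans(p[cl == c, , drop = FALSE]),
                     numeric(ncol(p))))
  se_m <- t(vapply(k, function(c) {
    sub <- p[cl == c, , drop = FALSE]
    if (nrow(sub) == 1) rep(0, ncol(p)) else
      apply(sub, 2, stats::sd) / sqrt(nrow(sub))
  }, numeric(ncol(p))))
  rownames(mean_m) <- rownames(se_m) <- paste0("cluster", k)
  colnames(mean_m) <- colnames(se_m) <- colnames(p)
  sizes <- as.integer(table(cl)[as.character(k)])
  names(sizes) <- paste0("cluster", k)
  list(mean = mean_m, se = se_m, sizes = sizes)
}
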