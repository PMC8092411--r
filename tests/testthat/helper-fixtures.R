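# shared fixtures and independent oracles, all built in code

# small omics matrix from a plain matrix
tiny_omics <- function(values, days, omic = "transcript", log_scale = FALSE) {
  n <- ncol(values)
  reps <- as.integer(ave(days, days, FUN = seq_along))
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n)), day = days,
                        replicate = reps, arm = "treated")
  rownames(values) <- rownames(values) %||% sprintf("f%d", seq_len(nrow(values)))
  tempomics::omics_matrix(values, rownames(values), samples,
                          omic = omic, log_scale = log_scale)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random connected weighted graph
random_weighted_graph <- function(n, p = 0.5, wmin = 0.1, wmax = 1) {
  g <- igraph::sample_gnp(n, p)
  while (!igraph::is_connected(g) || igraph::ecount(g) == 0) {
    g <- igraph::sample_gnp(n, p)
  }
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), wmin, wmax)
  g
}

# two K3 cliques joined by a floored bridge: unambiguous 2-community graph
two_clique_graph <- function(bridge = 1e-6) {
  el <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- c(rep(1, 6), bridge)
  g
}

# barbell of two triangles joined by a unit edge (all weights 1)
barbell_graph <- function() {
  el <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- rep(1, 7)
  g
}

# adjusted Rand index, computed from the contingency table
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (si - expected) / ((sa + sb) / 2 - expected)
}

# naive O(m^2) BH step-up: q_(k) = min over l >= k of min(1, m/l * p_(l))
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(m / seq(k, m) * ps[seq(k, m)]))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Fisher p by hypergeometric tail enumeration
fisher_enum_p <- function(counts) {
  r1 <- sum(counts[1, ]); c1 <- sum(counts[, 1]); n <- sum(counts)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(a_range, c1, n - c1, r1)
  obs <- stats::dhyper(counts[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# empirical AUC by exhaustive pair comparison
brute_force_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
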