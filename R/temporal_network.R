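#' Standardise per-feature temporal response profiles
#'
#' Builds the feature x day matrix of temporal responses that the
#' gene-to-gene similarity network is computed from. From a stacked
#' differential table the profile is the log2 fold change per day; from a
#' log-scale matrix it is the per-day replicate mean. Each profile is then
#' z-scored across days with the population sd; constant profiles cannot be
#' z-scored and are dropped with a report.
#'
#' @param x a stacked differential table (see [differential_table()]) or a
#'   log-scale [omics_matrix()].
#' @param feature_subset features to keep; when `x` is a differential table
#'   the default is every feature called up or down on at least one day.
#' @return list of class `temporal_profiles` with `profiles` (feature x
#'   day matrix, rows mean 0 / sd 1), `days`, and `dropped` (constant
#'   features removed).
#' @export
standardize_profiles <- function(x, feature_subset = NULL) {
  if (inherits(x, "omics_matrix")) {
    if (!x$log_scale) stop("matrix input must be log scale")
    days <- sort(unique(x$samples$day))
    if (length(days) < 3) stop("need at least 3 days")
    prof <- vapply(days, function(d) {
      rowMeans(x$values[, samples_at_day(x, d), drop = FALSE])
    }, numeric(nrow(x$values)))
    prof <- matrix(prof, nrow = nrow(x$values))
    rownames(prof) <- x$feature_ids
  } else {
    tab <- x
    days <- sort(unique(tab$day))
    if (length(days) < 3) stop("need at least 3 days")
    if (is.null(feature_subset)) {
      feature_subset <- unique(tab$feature_id[tab$call != "none"])
    }
    features <- unique(tab$feature_id)
    prof <- vapply(days, function(d) {
      sub <- tab[tab$day == d, ]
      sub$log2FC[match(features, sub$feature_id)]
    }, numeric(length(features)))
    prof <- matrix(prof, nrow = length(features))
    rownames(prof) <- features
  }
  colnames(prof) <- paste0("d", days)
  if (!is.null(feature_subset)) {
    if (length(feature_subset) == 0) stop("feature_subset is empty")
    prof <- prof[rownames(prof) %in% feature_subset, , drop = FALSE]
  }
  if (nrow(prof) == 0) stop("no features left to standardise")

  sds <- sqrt(rowMeans((prof - rowMeans(prof))^2))
  dropped <- rownames(prof)[sds == 0]
  prof <- prof[sds > 0, , drop = FALSE]
  prof <- t(apply(prof, 1, zscore_pop))
  colnames(prof) <- paste0("d", days)
  structure(list(profiles = prof, days = days, dropped = dropped),
            class = "temporal_profiles")
}

#' @export
print.temporal_profiles <- function(x, ...) {
  cat(sprintf("temporal_profiles: %d features x %d days (%d constant dropped)\n",
              nrow(x$profiles), length(x$days), length(x$dropped)))
  invisible(x)
}

#' Sparse similarity graph over temporal profiles
#'
#' Connects features whose day courses are similar. Pairwise similarity is
#' the Pearson correlation `s_ij` of z-scored profiles; the edge set is the
#' union of the minimum spanning tree of the correlation distance
#' `d_ij = sqrt(2 (1 - s_ij))` (which guarantees connectivity) and each
#' node's `k` nearest neighbours by that distance. Edge weights are
#' `max(s_ij, eps)` with `eps = 1e-6`, so bridging edges between
#' anticorrelated regions keep a positive, negligible weight.
#'
#' @param profiles a `temporal_profiles` object from
#'   [standardize_profiles()].
#' @param k number of nearest neighbours per node (>= 1, < number of
#'   features).
#' @param eps weight floor for non-positive similarities.
#' @return a connected, undirected, weighted [igraph::graph] whose vertex
#'   names are the feature IDs.
#' @export
similarity_graph <- function(profiles, k = 5, eps = 1e-6) {
  stopifnot(inherits(profiles, "temporal_profiles"))
  p <- profiles$profiles
  n <- nrow(p)
  if (n < 2) stop("need at least 2 features")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be < number of features")
  s <- stats::cor(t(p))
  d <- sqrt(pmax(2 * (1 - s), 0))
  diag(d) <- Inf

  # MST on the complete distance graph
  full <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(d), d, 0), mode = "undirected", weighted = TRUE,
    diag = FALSE)
  mst_edges <- igraph::as_edgelist(igraph::mst(full, weights = igraph::E(full)$weight),
                                   names = FALSE)

  # k nearest neighbours per node
  knn_edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    cbind(i, nb)
  }))
  edges <- rbind(mst_edges, knn_edges)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)

  w <- pmax(s[edges], eps)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- rownames(p)
  g
}
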