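#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are removed with a warning; lines with
#' fewer than three fields are an error naming the offending line.
#'
#' @param path GMT file path.
#' @return named list of character vectors of class `gene_set_collection`,
#'   with the per-set descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    }
    nm <- fields[1]
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    if (nm %in% names(sets)) stop("duplicate set name '", nm, "'")
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  structure(sets, description = descs, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Single-sample gene-set enrichment scores
#'
#' Rank-based KS running-sum score per sample and gene set: features are
#' ranked by expression in decreasing order (ties broken by feature ID for
#' determinism); walking down the ranking, the running sum gains
#' `1/|set|` at set members (weighted by `(n - position + 1)^alpha`,
#' renormalised, when `alpha > 0`) and loses `1/(n - |set|)` elsewhere.
#' The score is the maximum-magnitude deviation of the running sum, signed,
#' so a set concentrated at the top of the ranking scores towards `+1` and
#' one at the bottom towards `-1`. Sets with no overlap with the measured
#' features get `NA` and are reported via a warning.
#'
#' @param log_matrix an [omics_matrix()] (log scale).
#' @param sets a `gene_set_collection` or named list of feature-ID vectors.
#' @param alpha rank-weighting exponent (>= 0; 0 = unweighted KS statistic).
#' @return object of class `enrichment_matrix`: set x sample score matrix
#'   with attribute `scaled = FALSE`.
#' @export
sample_set_scores <- function(log_matrix, sets, alpha = 0) {
  stopifnot(inherits(log_matrix, "omics_matrix"))
  if (alpha < 0) stop("alpha must be >= 0")
  v <- log_matrix$values
  n <- nrow(v)
  ids <- log_matrix$feature_ids
  scores <- matrix(NA_real_, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  overlap <- lapply(sets, function(s) ids[ids %in% s])
  none <- vapply(overlap, length, integer(1)) == 0
  if (any(none)) {
    warning("set(s) with no overlapping features: ",
            paste(names(sets)[none], collapse = ", "))
  }
  for (j in seq_len(ncol(v))) {
    ord <- order(-v[, j], ids)  # decreasing expression, ties by feature_id
    ranked <- ids[ord]
    pos_weight <- (n - seq_len(n) + 1)^alpha
    for (k in which(!none)) {
      hit <- ranked %in% overlap[[k]]
      n_hit <- sum(hit)
      if (n_hit == n) { scores[k, j] <- 0; next }
      inc <- numeric(n)
      wh <- pos_weight[hit]
      inc[hit] <- wh / sum(wh)
      inc[!hit] <- -1 / (n - n_hit)
      run <- cumsum(inc)
      scores[k, j] <- run[which.max(abs(run))]
    }
  }
  structure(scores, scaled = FALSE, class = c("enrichment_matrix", "matrix"))
}

#' Scale enrichment scores to \[-1, 1\] per gene set
#'
#' Divides each set's scores by its maximum absolute score across samples,
#' so every non-zero set attains -1 or +1 in at least one sample; all-zero
#' rows are left unchanged.
#'
#' @param matrix an unscaled `enrichment_matrix`.
#' @return the matrix with every row in `[-1, 1]` and `scaled = TRUE`.
#' @export
scale_scores <- function(matrix) {
  if (isTRUE(attr(matrix, "scaled"))) stop("matrix is already scaled")
  m <- unclass(matrix)
  for (i in seq_len(nrow(m))) {
    mx <- max(abs(m[i, ]), na.rm = TRUE)
    if (is.finite(mx) && mx > 0) m[i, ] <- m[i, ] / mx
  }
  structure(m, scaled = TRUE, class = c("enrichment_matrix", "matrix"))
}
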