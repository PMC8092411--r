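#' Count cell lines dependent on a gene
#'
#' A line counts as dependent when its dependency probability for the gene
#' is strictly above `threshold`.
#'
#' @param prob_matrix gene x cell-line matrix of dependency probabilities
#'   (DepMap-portal layout: genes in rows, line IDs in columns).
#' @param gene gene to count.
#' @param threshold probability cutoff in (0, 1).
#' @return integer count.
#' @export
#' @examples
#' m <- matrix(c(0.9, 0.6, 0.5, 0.1, 0.4), 1,
#'             dimnames = list("EIF2AK4", paste0("L", 1:5)))
#' count_dependent(m, "EIF2AK4")  # 2; 0.5 is not > 0.5
count_dependent <- function(prob_matrix, gene, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!gene %in% rownames(prob_matrix)) stop("gene '", gene, "' not present")
  sum(prob_matrix[gene, ] > threshold)
}

#' Select extreme dependency groups, tissue-matched
#'
#' The top group holds the `n_top` most dependent lines (most negative
#' scores). The bottom group is drawn from the least dependent end, greedily
#' matching the tissue histogram of the top group: walking from the least
#' negative score downward, a line is taken while its tissue is still
#' under-represented relative to the top group. Tissues that cannot be
#' matched (absent or exhausted among the candidates) are reported as
#' shortfalls and back-filled from the global least-dependent pool.
#'
#' @param scores named numeric vector of dependency scores (CERES-like,
#'   more negative = more dependent), names = line IDs.
#' @param tissues named character vector of tissue labels for the same
#'   lines.
#' @param n_top,n_bottom group sizes; `n_top + n_bottom` at most the number
#'   of lines.
#' @return list with `top`, `bottom` (line IDs), and `shortfall` (named
#'   integer per tissue, 0 when the histogram matched).
#' @export
select_extreme_lines <- function(scores, tissues, n_top, n_bottom) {
  if (is.null(names(scores))) stop("scores must be named by line ID")
  if (any(!names(scores) %in% names(tissues))) stop("missing tissue labels")
  tissues <- tissues[names(scores)]
  if (any(is.na(tissues) | !nzchar(tissues))) stop("empty tissue labels")
  if (n_top + n_bottom > length(scores)) {
    stop("n_top + n_bottom exceeds the number of lines")
  }
  ord <- order(scores)  # most negative first
  top <- names(scores)[ord[seq_len(n_top)]]
  want <- table(tissues[top])
  # scale the target histogram to n_bottom lines
  target <- round(as.numeric(want) / sum(want) * n_bottom)
  names(target) <- names(want)
  while (sum(target) != n_bottom) {  # rounding drift
    i <- which.max(target)
    target[i] <- target[i] + sign(n_bottom - sum(target))
  }
  candidates <- setdiff(names(scores)[rev(ord)], top)  # least dependent first
  need <- target
  bottom <- character(0)
  for (id in candidates) {
    tis <- tissues[[id]]
    if (!is.na(need[tis]) && !is.null(need[tis]) && tis %in% names(need) &&
        need[tis] > 0) {
      bottom <- c(bottom, id)
      need[tis] <- need[tis] - 1
    }
    if (sum(need) == 0) break
  }
  shortfall <- need
  if (sum(need) > 0) {
    fill <- setdiff(candidates, bottom)[seq_len(sum(need))]
    bottom <- c(bottom, fill)
  }
  list(top = top, bottom = bottom, shortfall = shortfall)
}

#' Derive a dependency gene-expression signature from extreme groups
#'
#' Per-gene moderated t between the dependent and independent groups (see
#' [moderated_ttest()] machinery), BH adjustment, genes passing
#' `q <= q_max` ranked by absolute t, the top `size` retained. Direction is
#' the sign of (dependent mean - independent mean); ties in |t| are broken
#' by gene ID for determinism. When fewer than `size` genes pass the
#' threshold, all passing genes are returned and the signature is flagged
#' short.
#'
#' @param expr gene x line expression matrix (log scale).
#' @param groups list with `top` (dependent) and `bottom` (independent)
#'   line IDs, both of size >= 3 (e.g. from [select_extreme_lines()]).
#' @param size signature size (the profiled signatures used 56, 40 and 58
#'   genes for skin, CNS and liver).
#' @param q_max BH threshold.
#' @param target_gene recorded in the metadata.
#' @return object of class `dependency_signature`: list with `target`,
#'   `genes`, `direction` (+1 / -1 per gene), `stats` (t, q per gene),
#'   `flagged_short`, `metadata`.
#' @export
derive_signature <- function(expr, groups, size = 56, q_max = 0.05,
                             target_gene = "EIF2AK4") {
  if (length(groups$top) < 3 || length(groups$bottom) < 3) {
    stop("both groups need at least 3 lines")
  }
  x1 <- expr[, groups$top, drop = FALSE]
  x0 <- expr[, groups$bottom, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  d <- n1 + n0 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)) / d
  prior <- fit_variance_prior(s2, d)
  d0 <- prior[["d0"]]; s0sq <- prior[["s0sq"]]
  stilde2 <- if (is.finite(d0)) (d0 * s0sq + d * s2) / (d0 + d) else
    rep(s0sq, length(s2))
  se <- sqrt(stilde2 * (1 / n1 + 1 / n0))
  tt <- ifelse(se == 0, 0, (m1 - m0) / se)
  q <- bh_adjust(2 * stats::pt(-abs(tt), df = d0 + d))
  pass <- which(q <= q_max & tt != 0)
  ord <- pass[order(-abs(tt[pass]), rownames(expr)[pass])]
  flagged <- length(ord) < size
  keep <- ord[seq_len(min(size, length(ord)))]
  genes <- rownames(expr)[keep]
  structure(list(
    target = target_gene,
    genes = genes,
    direction = stats::setNames(as.integer(sign(tt[keep])), genes),
    stats = data.frame(gene = genes, t = unname(tt[keep]), q = unname(q[keep]),
                       stringsAsFactors = FALSE),
    flagged_short = flagged,
    metadata = list(n_dependent = n1, n_independent = n0, q_max = q_max,
                    size = size, n_passing = length(ord))
  ), class = "dependency_signature")
}

#' @export
print.dependency_signature <- function(x, ...) {
  cat(sprintf("dependency_signature[%s]: %d genes (%d up, %d down)%s\n",
              x$target, length(x$genes), sum(x$direction > 0),
              sum(x$direction < 0),
              if (x$flagged_short) " [FLAGGED: short]" else ""))
  invisible(x)
}

#' Project a dependency signature onto a tumor cohort
#'
#' Each signature gene is z-scored across the cohort; a tumor's match
#' fraction is the share of signature genes whose z-score sign agrees with
#' the signature direction. Tumors are classified dependent when the
#' fraction exceeds `match_thr` strictly (a fraction of exactly 0.8 at the
#' default threshold is not dependent).
#'
#' @param signature a `dependency_signature`.
#' @param tumor_expr gene x tumor expression matrix (>= 2 tumors); at least
#'   half the signature genes must be present.
#' @param match_thr classification threshold on the match fraction.
#' @return data.frame of class `projection_result`: `tumor_id`,
#'   `match_fraction`, `dependent`; attribute `"n_genes_used"`.
#' @export
project_signature <- function(signature, tumor_expr, match_thr = 0.8) {
  stopifnot(inherits(signature, "dependency_signature"))
  if (ncol(tumor_expr) < 2) stop("z-scores undefined for a cohort of 1 tumor")
  present <- intersect(signature$genes, rownames(tumor_expr))
  if (length(present) < length(signature$genes) / 2) {
    stop("fewer than half the signature genes present in the cohort")
  }
  sub <- tumor_expr[present, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  agree <- sign(z) == signature$direction[present]
  frac <- colMeans(agree)
  res <- data.frame(tumor_id = colnames(tumor_expr),
                    match_fraction = unname(frac),
                    dependent = unname(frac > match_thr),
                    stringsAsFactors = FALSE)
  attr(res, "n_genes_used") <- length(present)
  class(res) <- c("projection_result", "data.frame")
  res
}

#' Read a DepMap-portal-layout CSV
#'
#' Genes in rows (first column), cell-line IDs as the header row.
#'
#' @param path CSV path.
#' @return numeric matrix, genes x lines.
#' @export
read_depmap_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
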