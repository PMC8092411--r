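#' Log-normalise an omics matrix
#'
#' Transcript counts become `log2(CPM + 0.5)` (counts per million within
#' each sample); protein and metabolite intensities become log2 values
#' median-centred per sample. The result is flagged as log-scale.
#'
#' @param x an [omics_matrix()]; transcript input must be raw counts, other
#'   layers positive intensities.
#' @return An [omics_matrix()] with `log_scale = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(1000, rep(111, 9)), 10, 1,
#'             dimnames = list(paste0("g", 1:10), "s1"))
#' s <- data.frame(sample_id = "s1", day = 0, replicate = 1, arm = "a")
#' # library size 10^6 scales CPM back to the raw count here:
#' normalize_log(omics_matrix(m * 1000, samples = s, omic = "transcript"))
normalize_log <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$log_scale) stop("matrix is already log-scale")
  v <- x$values
  if (x$omic == "transcript") {
    if (any(v < 0)) stop("negative counts")
    lib <- colSums(v)
    if (any(lib == 0)) stop("zero library size in sample(s): ",
                            paste(colnames(v)[lib == 0], collapse = ", "))
    cpm <- sweep(v, 2, lib, "/") * 1e6
    out <- log2(cpm + 0.5)
  } else {
    if (any(v <= 0)) stop("intensities must be positive")
    lg <- log2(v)
    out <- sweep(lg, 2, apply(lg, 2, stats::median), "-")
  }
  omics_matrix(out, x$feature_ids, x$samples, omic = x$omic, log_scale = TRUE)
}

# method-of-moments fit of the scaled-inverse-chi-square variance prior:
# s2 / s0^2 ~ F(d, d0).  Returns c(d0, s0sq).
fit_variance_prior <- function(s2, d) {
  m <- mean(s2)
  v <- stats::var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0) return(c(d0 = Inf, s0sq = m))
  R <- v / m^2
  denom <- R * d - 2
  if (denom <= 0) return(c(d0 = Inf, s0sq = m))
  d0 <- (4 * R * d + 2 * d - 4) / denom
  d0 <- max(d0, 0.05)
  s0sq <- if (is.finite(d0) && d0 > 2) m * (d0 - 2) / d0 else m
  c(d0 = d0, s0sq = s0sq)
}

#' Moderated two-group t-test of one day against baseline
#'
#' Compares replicates at `day` with replicates at day 0 for every feature
#' of a log-scale matrix, shrinking per-feature pooled variances toward a
#' common prior fitted by the method of moments across features:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, with the moderated t on
#' `d0 + d` degrees of freedom.
#'
#' @param log_matrix an [omics_matrix()] with `log_scale = TRUE`.
#' @param day the post-baseline day to contrast (must be in the metadata).
#' @param arm optional treatment arm to restrict to.
#' @param prior optional fixed prior `c(d0 = ..., s0sq = ...)`; by default
#'   the prior is fitted across features. `d0 = 0` reduces to the ordinary
#'   pooled-variance two-sample t.
#' @return data.frame with `feature_id`, `day`, `log2FC` (mean day minus
#'   mean day 0), `t`, `p` (two-sided).
#' @export
moderated_ttest <- function(log_matrix, day, arm = NULL, prior = NULL) {
  stopifnot(inherits(log_matrix, "omics_matrix"))
  if (!log_matrix$log_scale) stop("run normalize_log() first")
  i0 <- samples_at_day(log_matrix, 0, arm)
  i1 <- samples_at_day(log_matrix, day, arm)
  if (length(i1) == 0) stop("day ", day, " not present in sample metadata")
  if (length(i0) < 2 || length(i1) < 2) {
    stop("need at least 2 replicates at day 0 and at day ", day)
  }
  x0 <- log_matrix$values[, i0, drop = FALSE]
  x1 <- log_matrix$values[, i1, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  ss <- rowSums((x0 - m0)^2) + rowSums((x1 - m1)^2)
  d <- n0 + n1 - 2
  s2 <- ss / d
  if (is.null(prior)) prior <- fit_variance_prior(s2, d)
  d0 <- prior[["d0"]]; s0sq <- prior[["s0sq"]]
  stilde2 <- if (is.finite(d0)) (d0 * s0sq + d * s2) / (d0 + d) else
    rep(s0sq, length(s2))
  lfc <- m1 - m0
  se <- sqrt(stilde2 * (1 / n0 + 1 / n1))
  tt <- ifelse(se == 0, 0, lfc / se)
  df <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(feature_id = log_matrix$feature_ids, day = day,
             log2FC = unname(lfc), t = unname(tt), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`, no missing values.
#' @return q-values on the same order, capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues)) stop("missing p-values")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call per-feature deregulation from q-values and fold changes
#'
#' Applies the study's cutoff semantics: a feature is called `up` when
#' `q <= q_max` and `log2FC >= lfc_min`, `down` when `q <= q_max` and
#' `log2FC <= -lfc_min`, otherwise `none`. The fold-change cutoff defaults
#' to `lfc_min = 1` (fold change > 2) for transcripts and 0 for the other
#' layers; `q_max` defaults to 0.05.
#'
#' @param table data.frame with `log2FC` and `p` columns (e.g. from
#'   [moderated_ttest()]); a `q` column is computed with [bh_adjust()] if
#'   absent.
#' @param q_max FDR cutoff.
#' @param lfc_min minimum absolute log2 fold change (>= 0).
#' @return the table with `q` and `call` columns added.
#' @export
call_deregulated <- function(table, q_max = 0.05, lfc_min = 1) {
  if (lfc_min < 0) stop("lfc_min must be >= 0")
  if (is.null(table$q)) table$q <- bh_adjust(table$p)
  call <- rep("none", nrow(table))
  call[table$q <= q_max & table$log2FC >= lfc_min] <- "up"
  call[table$q <= q_max & table$log2FC <= -lfc_min] <- "down"
  table$call <- call
  table
}

#' Build the per-day differential table for one omic layer
#'
#' Runs [moderated_ttest()] for every post-baseline day, adjusts p-values
#' per day with [bh_adjust()] and applies [call_deregulated()].
#'
#' @inheritParams moderated_ttest
#' @inheritParams call_deregulated
#' @return data.frame `feature_id, day, log2FC, t, p, q, call` stacked over
#'   days.
#' @export
differential_table <- function(log_matrix, q_max = 0.05,
                               lfc_min = if (log_matrix$omic == "transcript") 1 else 0,
                               arm = NULL) {
  days <- sort(setdiff(unique(log_matrix$samples$day), 0))
  do.call(rbind, lapply(days, function(d) {
    call_deregulated(moderated_ttest(log_matrix, d, arm),
                     q_max = q_max, lfc_min = lfc_min)
  }))
}

#' Direction-of-change enrichment in an annotated gene set
#'
#' Among features called up or down at `day`, tests whether the up/down
#' split differs between features inside and outside `annotation_set`
#' (two-sided Fisher exact test). The odds ratio reported is the sample
#' (cross-product) odds ratio.
#'
#' @param table differential table with `call` (see [call_deregulated()]).
#' @param annotation_set character vector of feature IDs (e.g. a
#'   mitochondrial gene list).
#' @param day which day's calls to test.
#' @return list with `counts` (2x2 matrix, up/down x in-set/background),
#'   `odds_ratio`, `p`, and `empty_margin` flag (when a margin is empty the
#'   test is vacuous: `p = 1`, `odds_ratio = NA`).
#' @export
direction_enrichment_test <- function(table, annotation_set, day) {
  sub <- table[table$day == day & table$call != "none", , drop = FALSE]
  in_set <- sub$feature_id %in% annotation_set
  counts <- matrix(c(sum(sub$call == "up" & in_set),
                     sum(sub$call == "down" & in_set),
                     sum(sub$call == "up" & !in_set),
                     sum(sub$call == "down" & !in_set)),
                   2, 2, dimnames = list(c("up", "down"),
                                         c("in_set", "background")))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(list(counts = counts, odds_ratio = NA_real_, p = 1,
                empty_margin = TRUE))
  }
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  p <- stats::fisher.test(counts)$p.value
  list(counts = counts, odds_ratio = or, p = p, empty_margin = FALSE)
}

#' Transcript-protein fold-change correlation at one day
#'
#' Pearson correlation between transcript and protein log2 fold changes at
#' `day`, over the features called up or down in either layer at that day.
#'
#' @param tx_table,prot_table differential tables sharing a feature
#'   namespace.
#' @param day day to compare.
#' @return list with `r`, `p`, `n`.
#' @export
crossomics_fc_correlation <- function(tx_table, prot_table, day) {
  tx <- tx_table[tx_table$day == day, , drop = FALSE]
  pr <- prot_table[prot_table$day == day, , drop = FALSE]
  if (nrow(tx) == 0 || nrow(pr) == 0) stop("day ", day, " missing from a table")
  shared <- intersect(tx$feature_id, pr$feature_id)
  tx <- tx[match(shared, tx$feature_id), ]
  pr <- pr[match(shared, pr$feature_id), ]
  keep <- tx$call != "none" | pr$call != "none"
  if (sum(keep) < 3) stop("fewer than 3 deregulated feature pairs at day ", day)
  ct <- stats::cor.test(tx$log2FC[keep], pr$log2FC[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Per-sample principal component scores
#'
#' Projects samples on the top principal components of the feature-centred
#' log matrix.
#'
#' @param log_matrix an [omics_matrix()] (log scale).
#' @param n_pc number of components.
#' @return list with `scores` (samples x n_pc) and `explained` (variance
#'   fractions per component).
#' @export
pca_scores <- function(log_matrix, n_pc = 2) {
  stopifnot(inherits(log_matrix, "omics_matrix"))
  v <- log_matrix$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (n_pc > min(dim(v))) stop("n_pc exceeds matrix rank bound")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       explained = expl[seq_len(n_pc)])
}
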