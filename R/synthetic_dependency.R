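#' Simulate a CRISPR dependency cohort with a planted expression signature
#'
#' Generates a two-class cell-line panel in a DepMap-portal-like layout:
#' CERES-style dependency scores for a target gene (dependent lines centred
#' at -1, independent lines at 0, both sd 0.2), matching dependency
#' probabilities, a gene x line expression matrix in which the planted
#' signature genes are shifted by `delta` (in residual-sd units, with
#' directions split between up and down) between classes, tissue labels, and
#' a tumor cohort carrying a planted fraction of dependent tumors.
#'
#' @param config a [dependency_cohort_config()].
#'
#' @return A list of class `dependency_cohort` with elements `scores` and
#'   `probs` (eIF2-alpha-kinase genes x lines), `expr` (genes x lines),
#'   `tissues` (named character), `tumor_expr` (genes x tumors),
#'   `truth_lines`, `truth_tumors` (logical, dependent or not),
#'   `signature_truth` (data.frame: `gene`, `direction`), `target_gene`,
#'   and `config`.
#' @export
#' @examples
#' coh <- simulate_dependency_cohort(
#'   dependency_cohort_config(n_lines = 40, n_genes = 200,
#'                            n_signature = 20, seed = 5))
#' table(coh$truth_lines)
simulate_dependency_cohort <- function(config = dependency_cohort_config()) {
  stopifnot(inherits(config, "dependency_cohort_config"))
  cfg <- config
  line_ids <- sprintf("CL%04d", seq_len(cfg$n_lines))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  tumor_ids <- sprintf("TCGA%04d", seq_len(cfg$n_tumors))

  set.seed(child_seed(cfg$seed, 1))
  truth_lines <- stats::runif(cfg$n_lines) < cfg$dependent_fraction
  tissues <- sample(cfg$tissues, cfg$n_lines, replace = TRUE)
  names(tissues) <- line_ids

  # CERES-like dependency scores: target gene bimodal, decoy kinases null
  set.seed(child_seed(cfg$seed, 2))
  decoys <- setdiff(c("EIF2AK1", "EIF2AK2", "EIF2AK3", "EIF2AK4"), cfg$target_gene)
  dep_genes <- c(cfg$target_gene, decoys)
  scores <- matrix(stats::rnorm(length(dep_genes) * cfg$n_lines, 0, 0.15),
                   length(dep_genes), cfg$n_lines,
                   dimnames = list(dep_genes, line_ids))
  scores[cfg$target_gene, ] <- stats::rnorm(cfg$n_lines,
                                            ifelse(truth_lines, -1, 0), 0.2)
  probs <- stats::plogis(-(scores + 0.5) / 0.1)

  # planted signature: first n_signature genes, half up / half down
  sig_genes <- gene_ids[seq_len(cfg$n_signature)]
  direction <- rep(c(1, -1), length.out = cfg$n_signature)
  names(direction) <- sig_genes

  plant_expr <- function(n_cols, ids, dependent, seed) {
    set.seed(seed)
    m <- matrix(stats::rnorm(cfg$n_genes * n_cols), cfg$n_genes, n_cols,
                dimnames = list(gene_ids, ids))
    shift <- outer(direction, ifelse(dependent, cfg$delta / 2, -cfg$delta / 2))
    m[sig_genes, ] <- m[sig_genes, ] + shift
    m
  }
  expr <- plant_expr(cfg$n_lines, line_ids, truth_lines, child_seed(cfg$seed, 3))

  set.seed(child_seed(cfg$seed, 4))
  truth_tumors <- stats::runif(cfg$n_tumors) < cfg$tumor_dependent_fraction
  tumor_expr <- plant_expr(cfg$n_tumors, tumor_ids, truth_tumors,
                           child_seed(cfg$seed, 5))

  names(truth_lines) <- line_ids
  names(truth_tumors) <- tumor_ids
  structure(list(scores = scores, probs = probs, expr = expr,
                 tissues = tissues, tumor_expr = tumor_expr,
                 truth_lines = truth_lines, truth_tumors = truth_tumors,
                 signature_truth = data.frame(gene = sig_genes,
                                              direction = unname(direction),
                                              stringsAsFactors = FALSE),
                 target_gene = cfg$target_gene, config = cfg),
            class = "dependency_cohort")
}

#' @rdname simulate_dependency_cohort
#' @param n_lines,n_genes,n_tumors cohort dimensions.
#' @param n_signature number of planted signature genes (<= `n_genes`).
#' @param delta between-class expression shift in residual-sd units.
#' @param dependent_fraction fraction of dependent cell lines.
#' @param tumor_dependent_fraction fraction of dependent tumors.
#' @param tissues tissue labels to sample lines from.
#' @param target_gene gene whose dependency defines the classes.
#' @param seed integer seed.
#' @export
dependency_cohort_config <- function(n_lines = 200, n_genes = 5000,
                                     n_signature = 60, delta = 1.5,
                                     dependent_fraction = 0.3,
                                     n_tumors = 150,
                                     tumor_dependent_fraction = 0.2,
                                     tissues = c("skin", "cns", "liver",
                                                 "lung", "breast"),
                                     target_gene = "EIF2AK4",
                                     seed = 1) {
  if (n_signature > n_genes) stop("n_signature must be <= n_genes")
  if (delta < 0) stop("delta must be >= 0")
  if (dependent_fraction < 0 || dependent_fraction > 1 ||
      tumor_dependent_fraction < 0 || tumor_dependent_fraction > 1) {
    stop("dependent fractions must be in [0,1]")
  }
  if (length(tissues) < 1) stop("need at least one tissue label")
  structure(as.list(environment()), class = "dependency_cohort_config")
}
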