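#' Validated configuration for the analysis pipelines
#'
#' Collects every stage knob, validating each against its module's
#' preconditions before any computation runs.
#'
#' @param q_max FDR cutoff for deregulation calls.
#' @param lfc_min_transcript,lfc_min_other absolute log2FC cutoffs.
#' @param k nearest-neighbour count of the similarity graph.
#' @param t_grid Markov-time grid.
#' @param n_restarts optimiser restarts per Markov time.
#' @param vi_max robustness threshold; `NULL` = `0.05 * log(n)` at run time.
#' @param alpha enrichment rank-weight exponent.
#' @param signature_size,match_thr dependency-signature knobs.
#' @param n_top,n_bottom extreme-group sizes.
#' @param dependency_threshold dependent-line probability cutoff.
#' @param seed integer seed funnelling all randomness.
#' @param out_dir output directory (`NULL` = no files written).
#' @param verbose log stage progress to stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(q_max = 0.05, lfc_min_transcript = 1,
                            lfc_min_other = 0, k = 5,
                            t_grid = logspace(1e-2, 1e2, 50),
                            n_restarts = 50, vi_max = NULL, alpha = 0,
                            signature_size = 56, match_thr = 0.8,
                            n_top = 61, n_bottom = 60,
                            dependency_threshold = 0.5,
                            seed = 1, out_dir = NULL, verbose = FALSE) {
  if (q_max <= 0 || q_max > 1) stop("q_max must be in (0,1]")
  if (lfc_min_transcript < 0 || lfc_min_other < 0) stop("lfc_min must be >= 0")
  if (k < 1) stop("k must be >= 1")
  if (length(t_grid) == 0 || any(diff(t_grid) <= 0) || any(t_grid <= 0)) {
    stop("t_grid must be positive and strictly increasing")
  }
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(vi_max) && vi_max < 0) stop("vi_max must be >= 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (signature_size < 1) stop("signature_size must be >= 1")
  if (match_thr < 0) stop("match_thr must be >= 0")
  if (n_top < 3 || n_bottom < 3) stop("extreme groups need >= 3 lines")
  if (dependency_threshold <= 0 || dependency_threshold >= 1) {
    stop("dependency_threshold must be in (0,1)")
  }
  if (!is.numeric(seed) || length(seed) != 1) stop("seed must be one number")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the stress-recovery time-course workflow
#'
#' End-to-end analysis of one multi-omics time course: log-normalisation,
#' per-day deregulation calling for every provided layer, deregulation
#' counts per day, PCA scores, the temporal similarity graph over
#' deregulated transcripts, the Markov-stability scan with robust-partition
#' selection, cluster mean profiles, optional single-sample enrichment and
#' optional supernatant exchange rates. All outputs are returned in a
#' bundle and, when `config$out_dir` is set, written as TSV/CSV/JSON.
#'
#' @param transcripts transcript [omics_matrix()] (counts), mandatory.
#' @param proteins,metabolites optional intensity matrices.
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param supernatant optional `supernatant_series` (or data.frame plus
#'   `cells`/`volume_ml` in the object) for exchange rates.
#' @param config a [pipeline_config()].
#' @return list of class `recovery_result` with `differential` (per layer),
#'   `counts` (deregulated per day per layer), `pca`, `graph`, `scan`,
#'   `partition`, `cluster_profiles`, `enrichment`, `exchange`, `manifest`.
#' @export
run_recovery <- function(transcripts, proteins = NULL, metabolites = NULL,
                         gene_sets = NULL, supernatant = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(transcripts, "omics_matrix"))
  stage <- function(...) stage_log(config$verbose, ...)
  layers <- list(transcript = transcripts)
  if (!is.null(proteins)) layers$protein <- proteins
  if (!is.null(metabolites)) layers$metabolite <- metabolites

  stage("normalising ", length(layers), " layer(s)")
  logm <- lapply(layers, function(x) if (x$log_scale) x else normalize_log(x))

  stage("differential calling")
  diff <- lapply(names(logm), function(nm) {
    lfc <- if (nm == "transcript") config$lfc_min_transcript else config$lfc_min_other
    differential_table(logm[[nm]], q_max = config$q_max, lfc_min = lfc)
  })
  names(diff) <- names(logm)

  counts <- do.call(rbind, lapply(names(diff), function(nm) {
    tab <- diff[[nm]]
    agg <- stats::aggregate(cbind(up = tab$call == "up",
                                  down = tab$call == "down"),
                            by = list(day = tab$day), FUN = sum)
    data.frame(omic = nm, agg, total = length(unique(tab$feature_id)))
  }))

  stage("PCA")
  pca <- lapply(logm, function(m) pca_scores(m, n_pc = min(2, ncol(m$values) - 1)))

  stage("temporal network over deregulated transcripts")
  dereg <- unique(diff$transcript$feature_id[diff$transcript$call != "none"])
  graph <- scan <- partition <- cluster_profiles <- NULL
  profiles <- NULL
  if (length(dereg) >= max(3, config$k + 1)) {
    profiles <- standardize_profiles(diff$transcript, dereg)
    graph <- similarity_graph(profiles, k = config$k)
    stage("stability scan over ", length(config$t_grid), " Markov times")
    scan <- scan_markov_times(graph, config$t_grid,
                              n_restarts = config$n_restarts,
                              seed = child_seed(config$seed, 101))
    vi_max <- config$vi_max %||% (0.05 * log(scan$n_nodes))
    partition <- select_robust_partition(scan, vi_max = vi_max)
    cluster_profiles <- cluster_mean_profiles(partition, profiles)
  } else {
    stage("too few deregulated transcripts for a network; skipping clustering")
  }

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    stage("single-sample enrichment of ", length(gene_sets), " sets")
    enrichment <- scale_scores(sample_set_scores(logm$transcript, gene_sets,
                                                 alpha = config$alpha))
  }

  exchange <- NULL
  if (!is.null(supernatant)) {
    stage("exchange rates")
    mets <- unique(supernatant$supernatant$metabolite)
    exchange <- lapply(mets, function(m) exchange_rates(supernatant, metabolite = m))
    names(exchange) <- mets
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tempomics")),
    seed = config$seed,
    layers = names(layers),
    n_deregulated_transcripts = length(dereg),
    n_clusters = if (!is.null(partition)) length(unique(partition)) else NA,
    selection_flagged = if (!is.null(partition)) attr(partition, "flagged") else NA,
    deregulated_counts = counts
  )
  result <- structure(
    list(differential = diff, counts = counts, pca = pca, graph = graph,
         scan = scan, partition = partition,
         cluster_profiles = cluster_profiles, profiles = profiles,
         enrichment = enrichment, exchange = exchange, manifest = manifest),
    class = "recovery_result")
  if (!is.null(config$out_dir)) write_recovery_result(result, config$out_dir)
  result
}

write_recovery_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$differential)) {
    utils::write.table(result$differential[[nm]],
                       file.path(out_dir, paste0("differential_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$counts, file.path(out_dir, "deregulated_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$graph)) {
    el <- igraph::as_edgelist(result$graph)
    utils::write.table(
      data.frame(id_i = el[, 1], id_j = el[, 2],
                 weight = igraph::E(result$graph)$weight),
      file.path(out_dir, "feature_graph.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$scan)) {
    utils::write.table(as.data.frame(result$scan),
                       file.path(out_dir, "stability_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$partition)) {
    utils::write.csv(data.frame(feature_id = names(result$partition),
                                cluster = as.integer(result$partition)),
                     file.path(out_dir, "partition.csv"), row.names = FALSE)
  }
  if (!is.null(result$enrichment)) {
    utils::write.table(data.frame(set = rownames(result$enrichment),
                                  unclass(result$enrichment),
                                  check.names = FALSE),
                       file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$exchange)) {
    for (m in names(result$exchange)) {
      utils::write.csv(result$exchange[[m]],
                       file.path(out_dir, paste0("exchange_", m, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Run the dependency-signature workflow
#'
#' Counts dependent lines for the target gene, selects the extreme
#' dependency groups (tissue-matched), derives the expression signature and
#' projects it onto the tumor cohort.
#'
#' @param cohort a `dependency_cohort` (see [simulate_dependency_cohort()])
#'   or a list with the same fields read from DepMap-portal-layout CSVs.
#' @param config a [pipeline_config()].
#' @return list of class `dependency_result` with `n_dependent_lines`,
#'   `groups`, `signature`, `projection`, `summary`, `manifest`.
#' @export
run_dependency <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("scores", "probs", "expr", "tissues", "tumor_expr", "target_gene")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) stop("cohort is missing: ", paste(missing, collapse = ", "))
  stage <- function(...) stage_log(config$verbose, ...)

  stage("counting dependent lines")
  n_dep <- count_dependent(cohort$probs, cohort$target_gene,
                           threshold = config$dependency_threshold)
  stage("selecting extreme groups")
  groups <- select_extreme_lines(cohort$scores[cohort$target_gene, ],
                                 cohort$tissues,
                                 n_top = config$n_top, n_bottom = config$n_bottom)
  stage("deriving signature")
  signature <- derive_signature(cohort$expr, groups,
                                size = config$signature_size,
                                q_max = config$q_max,
                                target_gene = cohort$target_gene)
  stage("projecting onto ", ncol(cohort$tumor_expr), " tumors")
  projection <- project_signature(signature, cohort$tumor_expr,
                                  match_thr = config$match_thr)
  summary <- list(
    n_lines = ncol(cohort$expr),
    n_dependent_lines = n_dep,
    n_tumors = nrow(projection),
    n_dependent_tumors = sum(projection$dependent),
    dependent_tumor_fraction = mean(projection$dependent),
    signature_size = length(signature$genes),
    signature_flagged_short = signature$flagged_short
  )
  manifest <- c(list(package_version =
                       as.character(utils::packageVersion("tempomics")),
                     seed = config$seed), summary)
  result <- structure(list(n_dependent_lines = n_dep, groups = groups,
                           signature = signature, projection = projection,
                           summary = summary, manifest = manifest),
                      class = "dependency_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(target = signature$target, members = signature$genes,
           directions = as.list(signature$direction),
           metadata = signature$metadata),
      file.path(config$out_dir, "signature.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.table(projection,
                       file.path(config$out_dir, "projection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Read / write a pipeline configuration as YAML or JSON
#' @param config a [pipeline_config()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  x$t_grid <- as.numeric(unlist(x$t_grid))
  do.call(pipeline_config, x)
}
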