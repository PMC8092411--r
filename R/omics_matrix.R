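#' Feature-by-sample matrix for one omic layer
#'
#' Container tying a numeric feature x sample matrix to per-sample metadata
#' (sampling day, replicate, treatment arm) and a layer tag. Transcript
#' matrices hold non-negative counts; protein and metabolite matrices hold
#' positive intensities, or log-intensities once [normalize_log()] has run.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique feature identifiers; defaults
#'   to `rownames(values)`.
#' @param samples data.frame with columns `sample_id`, `day`, `replicate`,
#'   `arm`, one row per column of `values`.
#' @param omic one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @param log_scale logical; `TRUE` once values are on the log2 scale.
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `feature_ids`, `samples`, `omic`, `log_scale`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' samples <- data.frame(sample_id = colnames(m), day = c(0, 0, 1, 1),
#'                       replicate = c(1, 2, 1, 2), arm = "treated")
#' omics_matrix(m, samples = samples, omic = "transcript")
omics_matrix <- function(values, feature_ids = rownames(values), samples,
                         omic = c("transcript", "protein", "metabolite"),
                         log_scale = FALSE) {
  omic <- match.arg(omic)
  values <- as.matrix(values)
  if (is.null(feature_ids)) stop("feature_ids are required (or rownames on `values`)")
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) stop("duplicate feature_ids are not allowed")
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) must equal nrow(values)")
  }
  required <- c("sample_id", "day", "replicate", "arm")
  if (!all(required %in% names(samples))) {
    stop("samples must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("nrow(samples) must equal ncol(values)")
  }
  if (omic == "transcript" && !log_scale) {
    if (any(values < 0)) stop("transcript counts must be non-negative")
  }
  rownames(values) <- feature_ids
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, feature_ids = feature_ids,
         samples = as.data.frame(samples), omic = omic,
         log_scale = isTRUE(log_scale)),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s%s]: %d features x %d samples, days {%s}\n",
              x$omic, if (x$log_scale) ", log2" else "",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$samples$day)), collapse = ",")))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Write / read an omics matrix as TSV plus a sample-metadata sidecar
#'
#' The matrix is written features x samples with a header row of sample IDs
#' and a `feature_id` first column; sample metadata goes to a sidecar CSV
#' (`sample_id`, `day`, `replicate`, `arm`).
#'
#' @param x an [omics_matrix()].
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path>.samples.csv`.
#' @return `write_omics_matrix` returns `path` invisibly;
#'   `read_omics_matrix` returns an [omics_matrix()].
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = x$feature_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(x$samples, paste0(path, ".samples.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_matrix
#' @param omic,log_scale layer tag and scale flag for the object read back.
#' @export
read_omics_matrix <- function(path, omic, log_scale = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.csv(paste0(path, ".samples.csv"), stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$feature_id
  omics_matrix(values, df$feature_id, samples, omic = omic, log_scale = log_scale)
}

# split sample columns by day (within one arm), used by the differential stage
samples_at_day <- function(x, day, arm = NULL) {
  keep <- x$samples$day == day
  if (!is.null(arm)) keep <- keep & x$samples$arm == arm
  which(keep)
}
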