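#' Read a gene expression matrix from TSV
#'
#' Reads a tab-separated expression table with gene (or probe) identifiers in
#' the first column and one column per sample. Values are expected on the log2
#' scale (see [check_log_scale()]). Rows sharing an identifier — typically
#' multiple array probes mapping to one gene — can be collapsed to a single
#' row per gene.
#'
#' Missing or non-numeric cells are rejected rather than imputed: the ssGSEA
#' ranks downstream are undefined for missing values, and silent imputation
#' would corrupt the score.
#'
#' @param path Path to a TSV file. First column: gene identifier; header row:
#'   sample identifiers.
#' @param collapse `"max_mean"` (default) keeps, among rows sharing an
#'   identifier, the row with the highest mean expression; `"none"` requires
#'   identifiers to be unique already.
#' @param transpose If `TRUE`, the file is samples-in-rows and is transposed
#'   after reading.
#' @return A numeric matrix, genes in rows, samples in columns, with unique
#'   `rownames` and the file's sample order preserved in `colnames`.
#' @seealso [write_expression()], [collapse_probes()]
#' @export
read_expression <- function(path, collapse = c("max_mean", "none"),
                            transpose = FALSE) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2) {
    abort(paste0("malformed header in ", path,
                 ": need a gene id column plus at least one sample column"))
  }
  if (nrow(raw) == 0) abort(paste0("no usable data rows in ", path))
  ids <- raw[[1]]
  samples <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE)
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric or missing value at gene '%s', sample '%s' (data line %d) in %s",
      ids[bad[1, 1]], samples[bad[1, 2]], bad[1, 1] + 1L, path))
  }
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  if (collapse == "max_mean") vals <- collapse_probes(vals)
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x, check_unique = FALSE)
  out <- tibble(gene_id = rownames(x))
  out <- dplyr::bind_cols(out, as_tibble(x, .name_repair = "minimal"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Collapse duplicate gene rows by maximum mean expression
#'
#' Among rows sharing a row name, keeps the row with the highest mean across
#' samples (ties broken toward the first occurrence). The operation is
#' idempotent and preserves the first-occurrence order of gene identifiers.
#'
#' @param x Numeric matrix with (possibly duplicated) row names.
#' @return The matrix with unique row names.
#' @export
collapse_probes <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) abort("matrix must have row names to collapse")
  if (!anyDuplicated(ids)) return(x)
  means <- rowMeans(x)
  keep <- tapply(seq_along(ids), factor(ids, levels = unique(ids)),
                 function(i) i[which.max(means[i])])
  x[as.integer(keep), , drop = FALSE]
}

validate_expression <- function(x, check_unique = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) abort("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix must have gene row names and sample column names")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("expression matrix needs at least 2 genes and 2 samples")
  }
  if (!all(is.finite(x))) abort("expression matrix contains non-finite values")
  if (check_unique && anyDuplicated(rownames(x))) {
    abort("duplicate gene ids; collapse probes first")
  }
  invisible(x)
}

#' Heuristic check that a matrix is on the log scale
#'
#' ssGSEA scoring assumes log-scale input. Linear-scale microarray or RNA-seq
#' matrices reach into the thousands, while log2 intensities rarely exceed
#' ~20, so a maximum above 50 flags a likely linear-scale matrix. The check
#' only reports; it never transforms the data.
#'
#' @param x Numeric expression matrix.
#' @param max_log Largest value still considered plausible for log-scale data.
#' @return A list with `max_value`, `plausible`, and a human-readable
#'   `message`; a warning is raised when the matrix looks linear-scale.
#' @export
check_log_scale <- function(x, max_log = 50) {
  mx <- max(x)
  ok <- mx <= max_log
  msg <- if (ok) {
    sprintf("log-scale: plausible (max value %.3g)", mx)
  } else {
    sprintf("values look linear-scale (max value %.3g > %g); log-transform before scoring",
            mx, max_log)
  }
  if (!ok) warn(msg)
  structure(list(max_value = mx, plausible = ok, message = msg),
            class = "log_scale_check")
}

#' @export
print.log_scale_check <- function(x, ...) {
  cat(x$message, "\n")
  invisible(x)
}

#' Read a sample annotation table from TSV
#'
#' Expected columns (all optional except `sample_id`): `egfr_status` (one of
#' `wild_type`, `hotspot_mutant`, `vus`, `other_mutant`, `unknown`),
#' `kras_status` (`wild_type`, `mutant`, `unknown`), `rfs_time`/`rfs_event`,
#' `os_time`/`os_event`, `shrinkage_rate`, `ic50`. Any further columns (e.g.
#' PD-L1 expression, mutation burden) are preserved as auxiliary per-sample
#' quantities.
#'
#' @param path Path to a TSV file with a `sample_id` column.
#' @return A tibble, one row per sample.
#' @export
read_sample_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (!"sample_id" %in% colnames(ann)) abort("annotation needs a sample_id column")
  if (anyDuplicated(ann$sample_id)) abort("duplicate sample_id in annotation")
  egfr_levels <- c("wild_type", "hotspot_mutant", "vus", "other_mutant", "unknown")
  if ("egfr_status" %in% colnames(ann)) {
    bad <- setdiff(unique(ann$egfr_status), c(egfr_levels, NA))
    if (length(bad) > 0) abort(paste0("unknown egfr_status value: ", bad[1]))
  }
  if ("kras_status" %in% colnames(ann)) {
    bad <- setdiff(unique(ann$kras_status), c("wild_type", "mutant", "unknown", NA))
    if (length(bad) > 0) abort(paste0("unknown kras_status value: ", bad[1]))
  }
  for (ep in c("rfs", "os")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (tcol %in% colnames(ann)) {
      if (!ecol %in% colnames(ann)) {
        abort(paste0(tcol, " present without ", ecol))
      }
      if (any(stats::na.omit(ann[[tcol]]) < 0)) abort(paste0(tcol, " must be non-negative"))
      if (any(!is.na(ann[[tcol]]) & is.na(ann[[ecol]]))) {
        abort(paste0(ecol, " missing where ", tcol, " is present"))
      }
    }
  }
  invisible(ann)
}
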