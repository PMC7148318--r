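#' Random-forest variable importance of candidate genes
#'
#' Grows a classification forest predicting mutant vs wild-type from the
#' expression of the candidate genes and returns each gene's variable
#' importance. The default metric is mean decrease in node impurity (Gini);
#' permutation importance (mean decrease in accuracy) is available as an
#' alternative.
#'
#' @param x Expression matrix, genes x samples.
#' @param mutant Logical vector over samples; both classes need >= 2 samples.
#' @param genes Optional character vector restricting the features (e.g. the
#'   DEG list); default: all rows of `x`.
#' @param n_trees Number of trees.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param metric `"gini"` (default) or `"permutation"`.
#' @return A tibble with `gene_id` and `importance` (non-negative), in gene
#'   order; `seed`, `n_trees` and `metric` are attached as attributes.
#' @export
rf_importance <- function(x, mutant, genes = NULL, n_trees = 500, seed = 1,
                          metric = c("gini", "permutation")) {
  metric <- match.arg(metric)
  validate_expression(x)
  if (length(mutant) != ncol(x)) abort("mutant must have one entry per sample")
  mutant <- as.logical(mutant)
  if (sum(mutant) < 2 || sum(!mutant) < 2) {
    abort("each class needs at least 2 samples")
  }
  genes <- genes %||% rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0) abort(paste0("gene not in matrix: ", missing[1]))
  feat <- t(x[genes, , drop = FALSE])
  y <- factor(ifelse(mutant, "mutant", "wild_type"),
              levels = c("wild_type", "mutant"))
  fit <- withr::with_seed(seed, randomForest::randomForest(
    feat, y, ntree = n_trees, importance = metric == "permutation"))
  imp_col <- if (metric == "gini") "MeanDecreaseGini" else "MeanDecreaseAccuracy"
  imp <- randomForest::importance(fit)[, imp_col]
  if (metric == "permutation") imp <- pmax(imp, 0)
  out <- tibble(gene_id = genes, importance = unname(imp[genes]))
  attr(out, "params") <- list(seed = seed, n_trees = n_trees, metric = metric)
  out
}

#' Select genes exceeding the third quartile of importance
#'
#' Drops genes with zero importance, computes the third quartile of the
#' remaining importances (linear-interpolation / type-7 quantile), and keeps
#' genes with importance strictly greater than it. The result is invariant
#' to the ordering of the input records.
#'
#' @param importance Tibble from [rf_importance()] with `gene_id` and
#'   `importance`.
#' @return Character vector of selected gene ids (input order).
#' @export
select_by_importance <- function(importance) {
  if (nrow(importance) == 0) abort("empty importance table")
  if (any(importance$importance < 0)) abort("importance must be non-negative")
  nz <- dplyr::filter(importance, .data$importance > 0)
  if (nrow(nz) == 0) abort("no informative genes: all importances are zero")
  q3 <- quantile(nz$importance, 0.75, type = 7, names = FALSE)
  sel <- nz$gene_id[nz$importance > q3]
  if (length(sel) == 0) {
    abort("empty selection: no gene exceeds the third quartile of importance")
  }
  sel
}

new_signature <- function(up, down, provenance = list()) {
  if (length(up) == 0 || length(down) == 0) {
    abort("both signature sides must be non-empty")
  }
  if (length(intersect(up, down)) > 0) {
    abort("up and down signatures must be disjoint")
  }
  structure(list(up_genes = up, down_genes = down, provenance = provenance),
            class = "egfr_signature")
}

#' Assemble the up/down EGFR signature from selected genes
#'
#' Partitions the selected genes by their differential-expression direction
#' (up in mutants vs down in mutants) and appends `append_down` — by default
#' the ALK gene, the canonical alternative driver whose expression marks
#' EGFR-independent tumors — to the downregulated side even when it is not a
#' DEG itself.
#'
#' @param selected Character vector of selected gene ids; every one must
#'   appear in `degs`.
#' @param degs Tibble from [moderated_t_test()] (or [filter_degs()]) holding
#'   at least `gene_id` and `direction`.
#' @param append_down Genes appended to the down set (deduplicated).
#' @param provenance Optional list recorded on the signature.
#' @return An `egfr_signature` with disjoint, non-empty `up_genes` and
#'   `down_genes`.
#' @export
assemble_signature <- function(selected, degs, append_down = "ALK",
                               provenance = list()) {
  missing <- setdiff(selected, degs$gene_id)
  if (length(missing) > 0) {
    abort(paste0("selected gene missing from DEG table: ", missing[1]))
  }
  dir <- degs$direction[match(selected, degs$gene_id)]
  up <- selected[dir == "up"]
  down <- selected[dir == "down"]
  down <- unique(c(down, append_down))
  new_signature(up, down,
                provenance = c(provenance, list(append_down = append_down)))
}

#' @export
print.egfr_signature <- function(x, ...) {
  cat(sprintf("EGFR signature: %d up, %d down\n",
              length(x$up_genes), length(x$down_genes)))
  cat("  up:  ", paste(head(x$up_genes, 10), collapse = ", "),
      if (length(x$up_genes) > 10) ", ..." else "", "\n", sep = "")
  cat("  down:", paste(head(x$down_genes, 10), collapse = ", "),
      if (length(x$down_genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Convert a signature to a two-set gene-set collection
#'
#' @param signature An `egfr_signature`.
#' @return Named list with elements `EGFR_UP` and `EGFR_DOWN`, suitable for
#'   [ssgsea()] or [write_gmt()].
#' @export
as_gene_sets <- function(signature) {
  stopifnot(inherits(signature, "egfr_signature"))
  list(EGFR_UP = signature$up_genes, EGFR_DOWN = signature$down_genes)
}

#' Derive the EGFR signature from a labeled cohort
#'
#' End-to-end derivation: excludes KRAS-mutant samples, restricts to samples
#' whose EGFR status is `hotspot_mutant` or `wild_type` (VUS/other/unknown
#' are uninformative for the mutant-vs-wild-type contrast and are dropped),
#' runs the moderated t-test, applies the p/fold-change DEG filter, ranks
#' DEGs by random-forest importance, keeps genes strictly above the third
#' quartile of nonzero importance, and assembles the signature.
#'
#' @param x Expression matrix, genes x samples (log2).
#' @param annotation Tibble with `sample_id`, `egfr_status`, `kras_status`.
#' @param p_max,fc_min DEG filter thresholds, see [filter_degs()].
#' @param n_trees,seed Forest parameters, see [rf_importance()].
#' @param append_down Genes appended to the down set; see
#'   [assemble_signature()].
#' @param moderation Passed to [moderated_t_test()].
#' @return An `egfr_signature` with full provenance (thresholds, seed,
#'   cohort size, DEG count).
#' @export
derive_signature <- function(x, annotation, p_max = 0.01, fc_min = 1.2,
                             n_trees = 500, seed = 1, append_down = "ALK",
                             moderation = TRUE) {
  flt <- exclude_kras_mutants(x, annotation)
  ann <- flt$annotation
  keep <- ann$egfr_status %in% c("hotspot_mutant", "wild_type")
  x2 <- flt$matrix[, keep, drop = FALSE]
  ann <- ann[keep, ]
  mutant <- ann$egfr_status == "hotspot_mutant"
  degs_all <- moderated_t_test(x2, mutant, moderation = moderation)
  degs <- filter_degs(degs_all, p_max = p_max, fc_min = fc_min)
  if (nrow(degs) == 0) abort("no DEGs at the given thresholds")
  imp <- rf_importance(x2, mutant, genes = degs$gene_id,
                       n_trees = n_trees, seed = seed)
  selected <- select_by_importance(imp)
  assemble_signature(
    selected, degs, append_down = append_down,
    provenance = list(p_max = p_max, fc_min = fc_min, n_trees = n_trees,
                      seed = seed, n_samples = ncol(x2),
                      n_mutant = sum(mutant), n_degs = nrow(degs)))
}
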