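#' Single-sample ssGSEA enrichment score for one sample
#'
#' Rank-weighted random-walk enrichment of a gene set within a single
#' sample's expression profile. All `N` genes are ranked within the sample
#' (ascending, so the most highly expressed gene has rank `N`; ties
#' averaged) and visited in decreasing-rank order. At step `i` the in-set
#' cumulative weight is
#' \deqn{P_{in}(i) = \frac{\sum_{g \in S,\ \mathrm{visited} \le i} r_g^\alpha}
#'                        {\sum_{g \in S} r_g^\alpha}}
#' and the out-of-set cumulative count is
#' \eqn{P_{out}(i) = \#\{g \notin S,\ \mathrm{visited} \le i\} / (N - |S|)};
#' the enrichment score is \eqn{ES = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]},
#' the summed (not maximal) deviation between the two walks.
#'
#' @param values Named numeric vector: one sample's expression over all
#'   genes, names = gene ids.
#' @param gene_set Character vector of gene ids; its intersection with
#'   `names(values)` and the complement must both be non-empty.
#' @param alpha Rank-weighting exponent, >= 0. `alpha = 0` weights all set
#'   genes equally.
#' @return The unnormalized enrichment score (scalar).
#' @export
ssgsea_sample_score <- function(values, gene_set, alpha = 0.25) {
  if (is.null(names(values))) abort("values must be named by gene id")
  if (alpha < 0) abort("alpha must be non-negative")
  in_set <- names(values) %in% gene_set
  n <- length(values)
  n_in <- sum(in_set)
  if (n_in == 0) abort("gene set has empty intersection with the profile")
  if (n_in == n) abort("gene set covers every gene; complement is empty")
  r <- rank(values, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  in_ord <- in_set[ord]
  w <- ifelse(in_ord, r[ord]^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out)
}

#' ssGSEA over a cohort and a gene-set collection
#'
#' Computes [ssgsea_sample_score()] for every set and sample. Set members
#' absent from the matrix are dropped with a warning. With
#' `normalize = TRUE` every score is divided by the range (max - min) of the
#' unnormalized score matrix, so normalized scores depend on the whole
#' cohort and set collection: adding samples or sets can change every score.
#' Use `normalize = FALSE` for cohort-independent scores.
#'
#' @param x Expression matrix (log2), genes x samples.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()] or
#'   [as_gene_sets()]), or an `egfr_signature`.
#' @param alpha Rank-weighting exponent; 0.25 is the conventional ssGSEA
#'   default.
#' @param normalize Divide by the global score range (default `TRUE`).
#' @return An `ssgsea_result`: list with `scores` (matrix, sets x samples),
#'   `params`, and `raw_range` (range of the unnormalized scores).
#' @export
ssgsea <- function(x, sets, alpha = 0.25, normalize = TRUE) {
  validate_expression(x)
  if (inherits(sets, "egfr_signature")) sets <- as_gene_sets(sets)
  if (length(sets) == 0) abort("need at least one gene set")
  if (is.null(names(sets))) abort("gene sets must be named")
  genes <- rownames(x)
  sets <- lapply(setNames(names(sets), names(sets)), function(nm) {
    s <- sets[[nm]]
    keep <- s %in% genes
    if (!all(keep)) {
      warn(sprintf("set '%s': %d gene(s) absent from the matrix dropped",
                   nm, sum(!keep)))
    }
    s <- s[keep]
    if (length(s) == 0) {
      abort(sprintf("set '%s' has empty intersection with the matrix", nm))
    }
    if (length(s) == nrow(x)) {
      abort(sprintf("set '%s' covers every gene; complement is empty", nm))
    }
    s
  })
  scores <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    vapply(sets, function(s) ssgsea_sample_score(col, s, alpha), numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), colnames(x)))
  raw_range <- max(scores) - min(scores)
  if (normalize) {
    if (raw_range == 0) {
      abort("degenerate score range: cannot normalize identical scores")
    }
    scores <- scores / raw_range
  }
  structure(
    list(scores = scores,
         params = list(alpha = alpha, normalize = normalize,
                       tie_method = "average"),
         raw_range = raw_range),
    class = "ssgsea_result")
}

#' @export
print.ssgsea_result <- function(x, ...) {
  cat(sprintf("ssGSEA result: %d set(s) x %d sample(s), alpha = %g, %s\n",
              nrow(x$scores), ncol(x$scores), x$params$alpha,
              if (x$params$normalize) "range-normalized" else "unnormalized"))
  invisible(x)
}

#' Tidy an ssGSEA result into long format
#'
#' @param x An `ssgsea_result`.
#' @param ... Unused.
#' @return A tibble with `set`, `sample_id`, `score`.
#' @export
tidy.ssgsea_result <- function(x, ...) {
  as_tibble(x$scores, rownames = "set") |>
    tidyr::pivot_longer(-"set", names_to = "sample_id", values_to = "score")
}
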