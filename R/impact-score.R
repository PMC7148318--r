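#' EGFR impact score
#'
#' The ratio of shifted enrichment scores,
#' \deqn{\mathrm{score} = \frac{ES_{up} + 1}{ES_{down} + 1},}
#' strictly increasing in the upregulated-signature enrichment and strictly
#' decreasing in the downregulated-signature enrichment. Range-normalized
#' ssGSEA scores lie well inside (-1, 1), so the +1 offsets keep both terms
#' positive; a nonpositive denominator signals a normalization fault and is
#' an error.
#'
#' @param es_up,es_down Enrichment scores of the up/down signatures
#'   (vectorized).
#' @return Numeric vector of impact scores.
#' @export
impact_score <- function(es_up, es_down) {
  stopifnot(length(es_up) == length(es_down))
  if (any(es_down + 1 <= 0)) {
    abort("denominator nonpositive: es_down + 1 must be > 0")
  }
  (es_up + 1) / (es_down + 1)
}

#' Score a cohort with an EGFR signature
#'
#' Runs ssGSEA for the up and down signatures over the cohort and combines
#' the per-sample enrichment scores into the EGFR impact score; optionally
#' classifies each sample against a threshold.
#'
#' @param x Expression matrix (log2), genes x samples.
#' @param signature An `egfr_signature`, or a named list whose first two
#'   sets are the up and down signatures.
#' @param alpha,normalize ssGSEA parameters, see [ssgsea()].
#' @param threshold Optional classification threshold (e.g. a published
#'   cutoff, or one calibrated with [calibrate_threshold()]); when supplied,
#'   the result includes the EI class.
#' @return A tibble with `sample_id`, `es_up`, `es_down`, `impact_score`
#'   (plus `ei_class` and `threshold` when a threshold is given). Scoring
#'   provenance (alpha, normalization, signature hash, threshold origin) is
#'   attached as `attr(, "provenance")`.
#' @export
score_cohort <- function(x, signature, alpha = 0.25, normalize = TRUE,
                         threshold = NULL) {
  sets <- if (inherits(signature, "egfr_signature")) {
    as_gene_sets(signature)
  } else {
    signature
  }
  if (length(sets) < 2) abort("need an up and a down signature")
  es <- ssgsea(x, sets[1:2], alpha = alpha, normalize = normalize)
  out <- tibble(
    sample_id = colnames(es$scores),
    es_up = es$scores[1, ],
    es_down = es$scores[2, ],
    impact_score = impact_score(es$scores[1, ], es$scores[2, ]))
  attr(out, "provenance") <- list(
    alpha = alpha, normalize = normalize, raw_range = es$raw_range,
    signature_hash = rlang::hash(sets[1:2]),
    threshold = threshold,
    threshold_origin = if (is.null(threshold)) NA_character_ else "supplied")
  if (!is.null(threshold)) out <- classify_impact(out, threshold)
  out
}

#' Calibrate the EI-H/EI-L threshold by ROC analysis
#'
#' Sweeps candidate thresholds over the midpoints between consecutive
#' distinct scores (plus -Inf/+Inf sentinels), classifying
#' `score > threshold` as positive, and picks the threshold maximizing
#' Youden's J = TPR - FPR (ties broken toward the smallest qualifying
#' threshold). The AUC is the trapezoidal area under the resulting ROC
#' curve.
#'
#' @param scores Numeric per-sample impact scores, or a tibble from
#'   [score_cohort()] (its `impact_score` column is used).
#' @param labels Logical (or coercible) per-sample truth, `TRUE` = positive
#'   class (e.g. EGFR hotspot mutant). Both classes must be present.
#' @return An `egfr_roc` object: the threshold sweep (`curve`), `auc`,
#'   chosen `threshold`, and `youden_j`. See [tidy.egfr_roc()],
#'   [glance.egfr_roc()], [autoplot.egfr_roc()].
#' @export
calibrate_threshold <- function(scores, labels) {
  if (is.data.frame(scores)) scores <- scores$impact_score
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  if (anyNA(scores) || anyNA(labels)) abort("missing scores or labels")
  if (!any(labels) || all(labels)) {
    abort("both label classes must be present")
  }
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores > t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !labels) / n_neg, numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  structure(
    list(curve = tibble(threshold = thr, tpr = tpr, fpr = fpr, youden = j),
         auc = auc, threshold = thr[best], youden_j = j[best],
         n_pos = n_pos, n_neg = n_neg),
    class = "egfr_roc")
}

#' @export
print.egfr_roc <- function(x, ...) {
  cat(sprintf("ROC calibration: AUC %.3f, threshold %.4g (Youden J %.3f), %d pos / %d neg\n",
              x$auc, x$threshold, x$youden_j, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy the ROC threshold sweep
#'
#' @param x An `egfr_roc`.
#' @param ... Unused.
#' @return A tibble with `threshold`, `tpr`, `fpr`, `youden`.
#' @export
tidy.egfr_roc <- function(x, ...) x$curve

#' One-row summary of a ROC calibration
#'
#' @param x An `egfr_roc`.
#' @param ... Unused.
#' @return A tibble with `auc`, `threshold`, `youden_j`, `n_pos`, `n_neg`.
#' @export
glance.egfr_roc <- function(x, ...) {
  tibble(auc = x$auc, threshold = x$threshold, youden_j = x$youden_j,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Classify samples into EI-H / EI-L
#'
#' Samples scoring strictly above the threshold are EI-H (high EGFR-pathway
#' impact); scores at or below it are EI-L. Ties at the threshold go to
#' EI-L.
#'
#' @param scores Tibble from [score_cohort()] (needs an `impact_score`
#'   column) or a numeric vector of impact scores.
#' @param threshold Finite classification threshold.
#' @return For tibble input: the tibble with `ei_class` (factor, levels
#'   `EI_H`, `EI_L`) and `threshold` columns added. For a numeric vector: a
#'   tibble with `impact_score`, `ei_class`, `threshold`.
#' @export
classify_impact <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort("threshold must be a single finite number")
  }
  if (!is.data.frame(scores)) {
    scores <- tibble(impact_score = as.numeric(scores))
  }
  cls <- factor(ifelse(scores$impact_score > threshold, "EI_H", "EI_L"),
                levels = c("EI_H", "EI_L"))
  dplyr::mutate(scores, ei_class = cls, threshold = threshold)
}
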