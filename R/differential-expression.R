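#' Drop KRAS-mutant samples from a cohort
#'
#' KRAS acts downstream of EGFR, so KRAS-mutant tumors can activate the same
#' transcriptional program without an EGFR mutation; they are removed before
#' the mutant-vs-wild-type differential comparison.
#'
#' @param x Expression matrix, genes x samples.
#' @param annotation Tibble with `sample_id` and `kras_status` columns
#'   covering every sample in `x`.
#' @return A list with the filtered `matrix` and `annotation` (sample order
#'   preserved).
#' @export
exclude_kras_mutants <- function(x, annotation) {
  validate_expression(x)
  missing <- setdiff(colnames(x), annotation$sample_id)
  if (length(missing) > 0) {
    abort(paste0("sample without annotation: ", missing[1]))
  }
  ann <- annotation[match(colnames(x), annotation$sample_id), ]
  keep <- is.na(ann$kras_status) | ann$kras_status != "mutant"
  if (!any(keep)) abort("no samples remain after excluding KRAS mutants")
  list(matrix = x[, keep, drop = FALSE], annotation = ann[keep, ])
}

#' Moderated t-test for two-group differential expression
#'
#' For each gene, computes the difference of group means on the log2 scale
#' and a t-statistic whose per-gene variance is shrunk toward a common prior
#' by empirical Bayes: with pooled variance \eqn{s_g^2} on \eqn{d_g = n_1 +
#' n_2 - 2} degrees of freedom and a scaled inverse-chi-square prior
#' \eqn{(d_0, s_0^2)},
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
#'       \tilde t_g = \frac{\bar x_{g,1} - \bar x_{g,2}}
#'                         {\tilde s_g \sqrt{1/n_1 + 1/n_2}},}
#' with two-sided p-values from the t distribution on \eqn{d_0 + d_g}
#' degrees of freedom. The prior is estimated from the distribution of
#' \eqn{\log s_g^2} by the method of moments (see [fit_variance_prior()]).
#'
#' @param x Expression matrix (log2), genes x samples.
#' @param mutant Logical vector over columns of `x`; `TRUE` marks the mutant
#'   (numerator) group. Both groups need at least 2 samples.
#' @param moderation If `FALSE`, no shrinkage is applied (`d0 = 0`): the
#'   statistic is the ordinary pooled-variance two-sample t.
#' @param prior Optional list with elements `d0` and `s0_sq` to use instead
#'   of the estimated prior; `d0 = Inf` replaces every gene variance by
#'   `s0_sq`.
#' @return A tibble with one row per gene: `gene_id`, `mean_mut`, `mean_wt`,
#'   `log_fc` (mutant minus wild-type, log2), `fold_change` (`2^log_fc`),
#'   `t_stat`, `p_value`, `p_adj` (Benjamini-Hochberg, informational only),
#'   `direction` (`"up"`/`"down"`). The fitted prior is attached as
#'   `attr(, "moderation")`.
#' @export
moderated_t_test <- function(x, mutant, moderation = TRUE, prior = NULL) {
  validate_expression(x)
  if (length(mutant) != ncol(x)) abort("mutant must have one entry per sample")
  if (anyNA(mutant)) abort("mutant labels must not be missing")
  mutant <- as.logical(mutant)
  n1 <- sum(mutant); n2 <- sum(!mutant)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")

  m1 <- unname(rowMeans(x[, mutant, drop = FALSE]))
  m2 <- unname(rowMeans(x[, !mutant, drop = FALSE]))
  v1 <- unname(apply(x[, mutant, drop = FALSE], 1, var))
  v2 <- unname(apply(x[, !mutant, drop = FALSE], 1, var))
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (!moderation) {
    prior <- list(d0 = 0, s0_sq = NA_real_)
  } else if (is.null(prior)) {
    prior <- fit_variance_prior(s2, df)
  }
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s0_sq + df * s2) / (d0 + df)
  }

  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  t_stat <- lfc / se
  df_total <- d0 + df
  p <- 2 * pt(-abs(t_stat), df = df_total)

  out <- tibble(
    gene_id = rownames(x),
    mean_mut = m1, mean_wt = m2,
    log_fc = lfc, fold_change = 2^lfc,
    t_stat = t_stat, p_value = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    direction = ifelse(lfc > 0, "up", "down"))
  attr(out, "moderation") <- list(d0 = d0, s0_sq = prior$s0_sq,
                                  per_gene_df = df, df_total = df_total,
                                  n_mut = n1, n_wt = n2)
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior \eqn{(d_0, s_0^2)} to observed
#' per-gene sample variances on `df` residual degrees of freedom by matching
#' the first two moments of \eqn{\log s_g^2}: with
#' \eqn{e_g = \log s_g^2 - \psi(d/2) + \log(d/2)},
#' \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)} determines \eqn{d_0}
#' (via a Newton inversion of the trigamma function) and
#' \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}. When the
#' observed spread is no larger than expected under a common variance, the
#' prior degenerates to `d0 = Inf` (all genes share `s0_sq`). Genes with zero
#' sample variance are excluded from the fit.
#'
#' @param s2 Per-gene pooled sample variances.
#' @param df Residual degrees of freedom (common to all genes).
#' @return A list with `d0`, `s0_sq`, and `per_gene_df`.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(df >= 1)
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) abort("all genes have zero sample variance; cannot fit prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- if (length(e) > 1) var(e) else 0
  excess <- e_var - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    # no excess spread beyond chi-square sampling noise: common variance,
    # estimated by the pooled (gamma-MLE) mean
    d0 <- Inf
    s0_sq <- mean(s2[is.finite(s2)])
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, per_gene_df = df)
}

# Newton inversion of trigamma on (0, Inf); y = trigamma(x), returns x.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Filter differential-expression records to DEGs
#'
#' Retains genes with `p_value < p_max` and linear fold change strictly
#' greater than `fc_min` or strictly smaller than `1/fc_min` (both
#' inequalities strict).
#'
#' @param degs Tibble from [moderated_t_test()].
#' @param p_max Raw p-value cutoff, in (0, 1].
#' @param fc_min Linear fold-change cutoff, > 1.
#' @return The filtered tibble.
#' @export
filter_degs <- function(degs, p_max = 0.01, fc_min = 1.2) {
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    abort("p_max must be in (0, 1]")
  }
  if (!is.numeric(fc_min) || fc_min <= 1) abort("fc_min must be > 1")
  dplyr::filter(degs, .data$p_value < p_max,
                .data$fold_change > fc_min | .data$fold_change < 1 / fc_min)
}
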