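#' Plot a ROC calibration curve
#'
#' ROC curve of the threshold sweep with the Youden-optimal operating point
#' marked.
#'
#' @param object An `egfr_roc` from [calibrate_threshold()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egfr_roc <- function(object, ...) {
  crv <- object$curve[order(object$curve$fpr, object$curve$tpr), ]
  best <- object$curve[which(object$curve$threshold == object$threshold), ]
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC calibration (AUC %.3f)", object$auc),
      subtitle = sprintf("threshold %.3g, Youden J %.3f",
                         object$threshold, object$youden_j)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object An `egfr_km` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of the per-group survival step functions.
#' @export
autoplot.egfr_km <- function(object, ...) {
  crv <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, survival = 1),
      .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability", colour = NULL,
      title = sprintf("%s by group", object$endpoint),
      subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of per-sample impact scores
#'
#' Samples ordered by decreasing impact score, optionally coloured by a
#' per-sample annotation (e.g. EGFR status), with the classification
#' threshold drawn when present.
#'
#' @param scores Tibble from [score_cohort()] / [classify_impact()].
#' @param colour_by Optional name of a column in `scores` to colour points
#'   by (join your annotation beforehand); default uses `ei_class` when
#'   available.
#' @return A ggplot.
#' @export
plot_impact_scores <- function(scores, colour_by = NULL) {
  colour_by <- colour_by %||%
    (if ("ei_class" %in% colnames(scores)) "ei_class" else NULL)
  dat <- dplyr::arrange(scores, dplyr::desc(.data$impact_score)) |>
    dplyr::mutate(rank = dplyr::row_number())
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank,
                                         y = .data$impact_score)) +
    ggplot2::labs(x = "Sample (ranked)", y = "EGFR impact score") +
    ggplot2::theme_minimal()
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]])) +
      ggplot2::labs(colour = colour_by)
  }
  if ("threshold" %in% colnames(dat) && nrow(dat) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = dat$threshold[1],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
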