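#' Welch two-sample t-test
#'
#' Unequal-variance comparison of a per-sample quantity (impact score,
#' PD-L1 expression, mutation burden, ...) between two groups, with the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param values_a,values_b Numeric vectors, each with >= 2 finite values.
#' @param group_a,group_b Group labels recorded in the output.
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(values_a, values_b, group_a = "A", group_b = "B") {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 finite values")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  tibble(group_a = group_a, group_b = group_b,
         n_a = length(values_a), n_b = length(values_b),
         mean_a = mean(values_a), mean_b = mean(values_b),
         t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' Association between the impact score and a continuous response (tumor
#' shrinkage rate, log IC50, ...).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A one-row tibble: `n`, `r`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble(n = length(x), r = unname(ht$estimate), p_value = ht$p.value)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time Non-negative follow-up times (months).
#' @param event Logical event indicator (TRUE = event, FALSE = censored).
#' @param group Two-level grouping (factor or coercible); both groups must
#'   be non-empty and at least one event must occur overall.
#' @param endpoint Label recorded on the result (e.g. `"RFS"`, `"OS"`).
#' @return An `egfr_km` object: per-group Kaplan-Meier step functions
#'   (`curves`: `group`, `time`, `n_risk`, `n_event`, `survival`), the
#'   log-rank chi-square statistic and p-value, and group sizes. See
#'   [tidy.egfr_km()], [glance.egfr_km()], [autoplot.egfr_km()].
#' @export
km_logrank <- function(time, event, group, endpoint = "RFS") {
  group <- factor(group)
  if (nlevels(group) != 2) abort("log-rank comparison needs exactly 2 groups")
  if (any(table(group) == 0)) abort("a group has zero subjects")
  if (length(time) != length(event) || length(time) != length(group)) {
    abort("time, event and group must have the same length")
  }
  event <- as.logical(event)
  if (!any(event)) abort("no events observed")
  if (any(time < 0)) abort("times must be non-negative")
  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ group)
  sd_ <- survival::survdiff(surv ~ group)
  stat <- unname(sd_$chisq)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  grp <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- tibble(group = grp, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
  structure(
    list(endpoint = endpoint, curves = curves, logrank_stat = stat,
         p_value = p, n = as.integer(table(group))),
    class = "egfr_km")
}

#' @export
print.egfr_km <- function(x, ...) {
  cat(sprintf("%s: log-rank chi-square %.3f, p = %.3g (n = %s)\n",
              x$endpoint, x$logrank_stat, x$p_value,
              paste(x$n, collapse = " / ")))
  invisible(x)
}

#' Tidy Kaplan-Meier curves
#'
#' @param x An `egfr_km`.
#' @param ... Unused.
#' @return The per-group step-function tibble.
#' @export
tidy.egfr_km <- function(x, ...) x$curves

#' One-row summary of a survival comparison
#'
#' @param x An `egfr_km`.
#' @param ... Unused.
#' @return A tibble with `endpoint`, `logrank_stat`, `p_value`, `n_total`.
#' @export
glance.egfr_km <- function(x, ...) {
  tibble(endpoint = x$endpoint, logrank_stat = x$logrank_stat,
         p_value = x$p_value, n_total = sum(x$n))
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron handling of tied event times (months
#' resolution ties heavily). Covariates are supplied as a data frame, e.g.
#' EGFR structural status alongside the EI class, to compare their
#' independent prognostic value.
#'
#' @param time,event Follow-up times and logical event indicators.
#' @param covariates Data frame of covariates (factors or numerics), one
#'   row per sample; must not be collinear.
#' @return An `egfr_cox` object wrapping the fit; [tidy.egfr_cox()] gives
#'   hazard ratios with 95% Wald intervals, [glance.egfr_cox()] the model
#'   summary.
#' @export
cox_multivariate <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) {
    abort("covariates must have one row per sample")
  }
  event <- as.logical(event)
  mm <- stats::model.matrix(~ ., data = covariates)
  if (qr(mm)$rank < ncol(mm)) {
    abort("collinear covariates: design matrix is rank-deficient")
  }
  if (sum(event) < ncol(mm)) {
    abort(sprintf("too few events (%d) for %d coefficient(s)",
                  sum(event), ncol(mm) - 1L))
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite|coefficient may be infinite",
                conditionMessage(w))) {
        abort(paste0("Cox fit failed: ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) {
    abort("Cox fit produced undefined coefficients (collinearity or separation)")
  }
  structure(list(fit = fit), class = "egfr_cox")
}

#' Hazard ratios from a Cox fit
#'
#' @param x An `egfr_cox`.
#' @param ... Unused.
#' @return A tibble with `term`, `hazard_ratio`, `conf_low`, `conf_high`
#'   (95% Wald), `p_value`.
#' @export
tidy.egfr_cox <- function(x, ...) {
  sm <- summary(x$fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  tibble(term = rownames(co),
         hazard_ratio = unname(co[, "exp(coef)"]),
         conf_low = unname(ci[, "lower .95"]),
         conf_high = unname(ci[, "upper .95"]),
         p_value = unname(co[, "Pr(>|z|)"]))
}

#' One-row summary of a Cox fit
#'
#' @param x An `egfr_cox`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `loglik`, `concordance`.
#' @export
glance.egfr_cox <- function(x, ...) {
  fit <- x$fit
  tibble(n = fit$n, n_events = fit$nevent,
         loglik = fit$loglik[2],
         concordance = unname(fit$concordance["concordance"]))
}

#' @export
print.egfr_cox <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}
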