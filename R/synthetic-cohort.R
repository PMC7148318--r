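#' Specify a synthetic two-group expression cohort
#'
#' Defines the generating parameters for [generate_cohort()]: a cohort of
#' EGFR-mutant and wild-type samples whose planted "up" genes are shifted
#' upward (and "down" genes downward) in mutant samples on a Gaussian
#' log2-intensity background, with exponential survival whose hazard depends
#' on the true class. Gaussian log-scale expression emulates RMA-normalised
#' microarray / log-scaled RNA-seq input; survival uses the simplest model
#' under which log-rank and Cox recovery are testable.
#'
#' @param n_samples Total number of samples.
#' @param mutant_fraction Fraction of EGFR-mutant samples, in (0, 1).
#' @param n_genes Total genes, planted plus noise.
#' @param n_up,n_down Number of planted up- and down-regulated genes.
#' @param effect Planted shift in log2 units (added to up genes and
#'   subtracted from down genes in mutant samples).
#' @param noise_sd Per-gene Gaussian noise SD, log2 units.
#' @param baseline_mean Baseline log2 intensity.
#' @param hazard_mutant,hazard_wildtype Exponential event hazards per month
#'   for the two true classes (applied to both RFS and OS times).
#' @param censor_hazard Hazard of an independent exponential censoring time.
#' @param max_followup Administrative censoring time, months.
#' @param kras_fraction Fraction of the wild-type EGFR samples carrying a
#'   KRAS mutation (exercises the KRAS-exclusion step).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 100, mutant_fraction = 0.2,
                           n_genes = 200, n_up = 10, n_down = 10,
                           effect = 2.0, noise_sd = 0.5, baseline_mean = 8,
                           hazard_mutant = 0.01, hazard_wildtype = 0.02,
                           censor_hazard = 0.008, max_followup = 60,
                           kras_fraction = 0, seed = 1) {
  stopifnot(n_samples >= 4, mutant_fraction > 0, mutant_fraction < 1,
            n_genes >= 2, n_up >= 0, n_down >= 0, is.finite(effect),
            noise_sd > 0, hazard_mutant > 0, hazard_wildtype > 0,
            censor_hazard >= 0, max_followup > 0,
            kras_fraction >= 0, kras_fraction < 1)
  if (n_up + n_down >= n_genes) {
    abort("planted gene count must be smaller than n_genes")
  }
  n_mut <- round(n_samples * mutant_fraction)
  if (n_mut < 2 || n_samples - n_mut < 2) {
    abort("mutant_fraction leaves fewer than 2 samples in a class")
  }
  structure(
    list(n_samples = n_samples, mutant_fraction = mutant_fraction,
         n_genes = n_genes, n_up = n_up, n_down = n_down, effect = effect,
         noise_sd = noise_sd, baseline_mean = baseline_mean,
         hazard_mutant = hazard_mutant, hazard_wildtype = hazard_wildtype,
         censor_hazard = censor_hazard, max_followup = max_followup,
         kras_fraction = kras_fraction, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws `n_genes x n_samples` log2 expression values
#' `Normal(baseline_mean, noise_sd)`, shifts the planted up/down genes by
#' `+/- effect` in mutant samples, and attaches an annotation table with EGFR
#' and KRAS status plus exponential RFS/OS times censored by the minimum of
#' an independent exponential censoring time and `max_followup`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_cohort` list with elements `matrix` (genes x
#'   samples), `annotation` (tibble), and `truth` (planted gene lists,
#'   per-sample true class, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec, sample_prefix = "S",
                                 all_mutant = FALSE, effect = NULL) {
  effect <- effect %||% spec$effect
  n <- spec$n_samples
  n_mut <- if (all_mutant) n else round(n * spec$mutant_fraction)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  up <- genes[seq_len(spec$n_up)]
  down <- genes[spec$n_up + seq_len(spec$n_down)]
  samples <- sprintf("%s%03d", sample_prefix, seq_len(n))
  is_mut <- c(rep(TRUE, n_mut), rep(FALSE, n - n_mut))

  x <- matrix(stats::rnorm(spec$n_genes * n, spec$baseline_mean, spec$noise_sd),
              nrow = spec$n_genes, dimnames = list(genes, samples))
  if (n_mut > 0) {
    x[up, is_mut] <- x[up, is_mut] + effect
    x[down, is_mut] <- x[down, is_mut] - effect
  }

  hazard <- ifelse(is_mut, spec$hazard_mutant, spec$hazard_wildtype)
  surv <- function() {
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- if (spec$censor_hazard > 0) {
      stats::rexp(n, rate = spec$censor_hazard)
    } else {
      rep(Inf, n)
    }
    t_cens <- pmin(t_cens, spec$max_followup)
    list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
  }
  rfs <- surv()
  os <- surv()

  kras <- rep("wild_type", n)
  wt_idx <- which(!is_mut)
  n_kras <- round(length(wt_idx) * spec$kras_fraction)
  if (n_kras > 0) kras[sample(wt_idx, n_kras)] <- "mutant"

  annotation <- tibble(
    sample_id = samples,
    egfr_status = ifelse(is_mut, "hotspot_mutant", "wild_type"),
    kras_status = kras,
    rfs_time = rfs$time, rfs_event = rfs$event,
    os_time = os$time, os_event = os$event)

  structure(
    list(matrix = x, annotation = annotation,
         truth = list(up_genes = up, down_genes = down,
                      mutant = setNames(is_mut, samples), spec = spec)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples (%d mutant), %d+%d planted genes, effect %.2g log2\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$truth$mutant),
              length(x$truth$up_genes), length(x$truth$down_genes),
              x$truth$spec$effect))
  invisible(x)
}

#' Truth signature of a synthetic cohort
#'
#' The planted up/down gene sets of a [generate_cohort()] result, packaged as
#' a signature object usable with [score_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @return An `egfr_signature`.
#' @export
truth_signature <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  new_signature(cohort$truth$up_genes, cohort$truth$down_genes,
                provenance = list(source = "synthetic truth",
                                  seed = cohort$truth$spec$seed))
}

#' Generate a sensitive/resistant cohort pair
#'
#' Emulates the contrast between a TKI-sensitive EGFR-mutant cell line and a
#' resistant derivative in which EGFR-pathway signature activation is lost:
#' both cohorts share genes and parameters; every sample is "activated"
#' (planted genes shifted by `effect`) in the sensitive cohort, while in the
#' resistant cohort the shift is attenuated to `attenuation * effect`.
#'
#' @param spec A [synthetic_spec()]; `n_samples` is the size of each cohort.
#' @param attenuation Fraction of the planted effect retained in the
#'   resistant cohort, in \[0, 1\]. 1 makes the two cohorts exchangeable; 0
#'   removes activation entirely.
#' @return A list with `sensitive` and `resistant` `synthetic_cohort`s.
#' @export
generate_resistant_pair <- function(spec, attenuation = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"),
            attenuation >= 0, attenuation <= 1)
  withr::with_seed(spec$seed, {
    sens <- generate_cohort_impl(spec, sample_prefix = "SEN",
                                 all_mutant = TRUE)
    res <- generate_cohort_impl(spec, sample_prefix = "RES",
                                all_mutant = TRUE,
                                effect = spec$effect * attenuation)
    list(sensitive = sens, resistant = res)
  })
}
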