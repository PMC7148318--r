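---
title: "The EGFR impact score: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The EGFR impact score: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrimpact)
```

# The problem

EGFR-mutant lung adenocarcinoma is usually identified structurally, by a
hotspot mutation call. But the quantity that actually predicts TKI response
and prognosis is *pathway dependency* — whether the tumor's transcriptional
state is dominated by EGFR signaling — and structural status is an
imperfect proxy for it in both directions: resistant derivatives of mutant
lines keep the mutation while losing dependency, and occasional wild-type
or VUS tumors are transcriptionally EGFR-driven. `egfrimpact` estimates
dependency directly from the expression profile.

# The model

## Signature derivation

The derivation cohort is a genes × samples log2 expression matrix with
per-sample EGFR and KRAS mutation status. Because KRAS sits downstream of
EGFR and activates an overlapping program, KRAS-mutant samples are excluded
before the contrast (`exclude_kras_mutants()`). Samples whose EGFR status
is a VUS, another non-hotspot variant, or unknown are also dropped from the
derivation contrast: they carry no usable label for the mutant-vs-wild-type
comparison.

Differential expression uses a moderated two-sample t: per-gene pooled
variances $s_g^2$ on $d_g = n_1 + n_2 - 2$ df are shrunk toward a prior
$(d_0, s_0^2)$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  \tilde t_g = \frac{\bar x_{g,\mathrm{mut}} - \bar x_{g,\mathrm{wt}}}
                    {\tilde s_g\sqrt{1/n_1 + 1/n_2}},$$

with two-sided p-values on $d_0 + d_g$ df. The prior is fit by the method
of moments on $\log s_g^2$ under a scaled inverse-chi-square model
(`fit_variance_prior()`); when the observed spread of log variances does
not exceed chi-square sampling noise the prior degenerates to a common
variance ($d_0 = \infty$, $s_0^2$ = pooled mean variance). `moderation =
FALSE` (equivalently $d_0 = 0$) gives the ordinary pooled t so the effect
of shrinkage can be quantified. DEGs are genes with raw $p < 0.01$ **and**
linear fold change $> 1.2$ or $< 1/1.2$, both inequalities strict; fold
change is $2^{\Delta}$ of the log2 mean difference. No multiple-testing
correction enters the filter (a BH column is emitted for information only):
the definition is a fixed selection rule, not an inference.

DEGs are then ranked by random-forest variable importance (500 trees, mean
decrease in Gini impurity — the default impurity metric of classification
forests; permutation importance is available as an option), predicting
mutant vs wild-type on the KRAS-excluded cohort. Genes with zero importance
are removed; of the rest, genes **strictly above the third quartile**
(type-7, linear-interpolation quantile — the convention matters at the
boundary) are selected and partitioned into the up- and downregulated
signatures by their DEG direction. *ALK* — the canonical alternative driver,
whose expression marks EGFR-independent biology — is appended to the
downregulated set even though it need not be a DEG. The forest is seeded
and the seed recorded in the signature provenance; selections vary across
seeds, and we treat a seed as part of the derivation definition rather than
averaging over seeds.

Two deliberate error conditions: if every nonzero importance is identical
(or only one gene remains), the strict quantile rule selects nothing and we
raise an error rather than silently falling back to a weaker rule; the same
if all importances are zero.

## Per-sample scoring

Single-sample GSEA is implemented from scratch (`ssgsea_sample_score()`).
Within one sample, all $N$ genes are ranked ascending (highest expression =
rank $N$, ties averaged) and visited in decreasing-rank order. The in-set
walk accumulates weights $r_g^\alpha$ normalized by the set total; the
out-set walk accumulates counts normalized by $N - |S|$; the enrichment
score is the *sum* of the gap over all $N$ positions (not the maximal
deviation of classical GSEA):

$$ES = \sum_{i=1}^{N}\left[P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\right].$$

Defaults: $\alpha = 0.25$ and division of the whole score matrix by its
range (max − min), the conventional ssGSEA settings. Both are recorded in
the scoring provenance because they materially change the numbers entering
the ratio below. Two consequences are worth stating plainly:

* **Cohort dependence.** Range normalization makes a sample's score depend
  on every other sample (and set) scored with it. Applying a threshold
  calibrated in one cohort to another implicitly assumes comparable
  normalization; `normalize = FALSE` gives cohort-independent raw scores
  when that assumption is untenable.
* **Rank invariance.** Scores depend on a sample's column only through
  ranks, so any strictly increasing per-sample transform (e.g. a different
  log base) leaves them unchanged; this is tested as a property.

Ties are average-ranked, which keeps scores invariant to gene order.
Missing values are rejected at I/O time rather than imputed, because ranks
are undefined for missing cells.

The **EGFR impact score** is
$(ES_{\mathrm{up}} + 1)/(ES_{\mathrm{down}} + 1)$: strictly increasing in
up-signature enrichment, strictly decreasing in down-signature enrichment,
equal to 1 when the two are balanced. Range-normalized scores lie well
inside $(-1, 1)$, so both terms stay positive; a nonpositive denominator is
treated as a normalization fault and raises an error.

## Threshold calibration and classification

`calibrate_threshold()` sweeps all midpoints between consecutive distinct
scores (plus $\pm\infty$ sentinels), classifying score > threshold as
positive, and chooses the threshold maximizing Youden's $J =
\mathrm{TPR} - \mathrm{FPR}$; ties go to the smallest qualifying
threshold, and the AUC is the trapezoidal area under the sweep. Youden's J
is one standard operating-point criterion among several; it is recorded in
the result so an alternative (e.g. closest-to-(0,1)) could be swapped in
without ambiguity about what was used. The calibration truth is an
explicit input — in a derivation cohort the natural dichotomy is EGFR
hotspot mutant vs wild-type. Classification assigns EI-H strictly above
the threshold and EI-L at or below it: the published class definitions
("higher than" / "lower than" the cutoff) leave equality undefined, and we
resolve ties downward, once, package-wide. A pre-calibrated cutoff can be
passed straight to `score_cohort(threshold =)` for external cohorts.

## Evaluation statistics

Group contrasts use Welch's t (unequal variances, Satterthwaite df);
score–response associations use Pearson's correlation with the t-transform
p-value; survival uses Kaplan–Meier curves with the two-group log-rank
test and Cox proportional-hazards models with Efron tie handling (survival
times at month resolution tie heavily, and Efron is the better
approximation under heavy ties). These are standard estimators and are
delegated to `stats` and `survival`; the package's own tests still verify
them against textbook formulas and simulations, because they sit inside
the pipeline's contract. PD-L1 expression and mutation-burden comparisons
are the same Welch contrast applied to auxiliary per-sample columns, not
separate code paths.

# The synthetic-cohort generator

`synthetic_spec()` / `generate_cohort()` emulate the statistical structure
the pipeline assumes: genes are independent Gaussians on the log2 scale
(baseline 8, SD 0.5 — typical RMA-normalized intensity scales), with
planted up/down genes shifted by ±2 log2 units in mutant samples; survival
is exponential with class-dependent hazard (mutant 0.01/month, wild-type
0.02/month — a 2× hazard ratio, median ~35 vs ~69 months), censored by the
minimum of an independent exponential (0.008/month) and a 60-month
administrative cutoff, giving realistic ~40–60% event fractions for an
early-stage cohort with limited follow-up. Defaults: 100 samples, 20%
mutant, 200 genes of which 10 up + 10 down are planted. Everything is a
deterministic function of the spec, including its seed.

`generate_resistant_pair()` emulates the sensitive-vs-resistant cell-line
contrast: two cohorts sharing genes and parameters, every sample
"activated", with the planted shift attenuated by a factor in the
resistant cohort (attenuation 1 = exchangeable null; 0 = complete loss of
pathway activation).

What the generator deliberately does **not** model: gene–gene correlation
(real signatures are co-regulated modules; independence makes planted
genes individually informative, which flatters per-gene power but is
conservative for forest importance spread), probe-level structure,
batch/platform effects, and non-Gaussian RNA-seq count noise. Passing the
synthetic benchmarks therefore demonstrates internal correctness of the
pipeline — each stage computes what it claims on data satisfying its
assumptions — not performance on any real cohort.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle computed
by a different route: a quadratic-time re-enumeration of both ssGSEA walks
(1,000 random 8-gene instances, agreement to 1e-12, plus hand-enumerated
4-gene cases with ES = ±2); scalar per-gene evaluation of the moderated-t
formulas (50-gene matrices, 1e-10) and a cross-check of the full
empirical-Bayes fit against the limma package; textbook Welch and
hand-derived Kaplan–Meier values; permutation nulls for the ROC sweep
(AUC ≈ 0.5) and Cox (log-HR ≈ 0); and parameter-recovery simulations
(Pearson ρ = 0.7; log-rank under a 3× hazard; Cox HR = 2).

End-to-end synthetic benchmarks use 20 cohorts (seeds fixed) at the default
spec for derivation and classification, 100 seed replicates of the
20+20-sample resistant pair, and 40 replicates of a 200-sample survival
cohort. The survival benchmark uses balanced classes (50/50): with a 2×
hazard ratio and ~110 events, a 20/80 allocation has normal-approximation
log-rank power ≈ 0.82 while 50/50 gives ≈ 0.92, and the benchmark is meant
to measure pipeline correctness at a design where the effect is reliably
detectable, not allocation-driven power loss.

One benchmark outcome deserves honest emphasis. With 10+10 planted genes
at a 2 log2-unit effect among 180 noise genes, the DEG stage recovers
essentially all 20 planted genes and admits only ~1–2 false positives, so
the DEG list is ~22 genes of almost pure signal. The above-Q3 selection
rule then retains at most a quarter of the nonzero-importance genes —
that is what "exceeding the third quartile" means — so the derived
signature contains ~5 genes and *cannot* recover the majority of the
planted set, however strong the signal. Every selected gene does land on
its planted side, and the resulting 5-gene signature still classifies the
cohort perfectly. The quartile rule is a fixed feature of the method, so
we report signature *size* and *side-correctness* as the meaningful
derivation metrics, and planted-gene recovery as the (rule-capped)
quantity it is.

# Numerical choices and degenerate inputs

* Quantiles are type-7 throughout; quartile conventions move boundary
  genes.
* Probe collapsing keeps the highest-mean row per gene id,
  deterministically (ties to first occurrence), and is idempotent.
* The trigamma inversion inside the prior fit is a Newton iteration with
  asymptotic guards at both ends; the degenerate branches ($d_0 = \infty$,
  all-zero variances) are explicit.
* Zero-variance genes: under moderation they get a finite statistic
  (shrinkage keeps $\tilde s^2 > 0$); with moderation off the statistic is
  undefined (0/0) or infinite and is returned as such rather than masked.
* Degenerate ssGSEA inputs (set covering no or all matrix genes, zero
  score range under normalization) and single-class calibration labels are
  errors, not warnings.
* A matrix whose maximum exceeds 50 is flagged as likely linear-scale
  (`check_log_scale()`); the check never transforms data.

# Known limitations

Threshold portability across cohorts is limited by cohort-range
normalization (above). The derived signature is seed-dependent through the
forest; provenance records the seed. Log-rank is two-group only;
proportional-hazards diagnostics, competing risks and time-varying
covariates are out of scope, as are probe annotation, normalization of raw
arrays, and any cohort downloading.
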