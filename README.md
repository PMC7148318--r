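# egfrimpact

Transcriptome-based scoring of EGFR-pathway dependency in lung
adenocarcinoma.

A hotspot mutation call (exon 19 del, L858R) is a coarse readout of whether
a tumor is actually driven by EGFR signaling: some mutant tumors have lost
pure EGFR dependency (and with it, TKI sensitivity), some wild-type or
VUS-carrying tumors behave like EGFR-driven ones. `egfrimpact` implements a
diagnostic score that reads pathway dependency off the expression profile
instead:

1. **Signature derivation.** In a cohort with known EGFR/KRAS mutation
   status, KRAS-mutant samples are excluded and differentially expressed
   genes between EGFR-mutant and wild-type tumors are called with a
   moderated t-statistic (empirical-Bayes variance shrinkage; DEG rule
   p < 0.01 and linear fold change > 1.2 or < 1/1.2). DEGs are ranked by
   random-forest variable importance (mean decrease in Gini impurity);
   genes with zero importance are dropped and those strictly above the
   third quartile of the rest are kept, split into an **upregulated** and a
   **downregulated** signature by their DEG direction, with *ALK* appended
   to the downregulated set.
2. **Per-sample scoring.** Each signature is scored in each sample by
   single-sample GSEA — the rank-weighted random-walk statistic
   ES = Σᵢ [P_in(i) − P_out(i)] with weight rankᵅ (α = 0.25) and
   cohort-range normalization — and combined into the **EGFR impact
   score**

   score = (ES_up + 1) / (ES_down + 1).

3. **Classification.** A threshold on the score is calibrated by ROC
   analysis (Youden's J = TPR − FPR, maximized over the threshold sweep);
   samples strictly above it are **EI-H** (high EGFR-pathway impact),
   the rest **EI-L**. A pre-calibrated cutoff can be supplied instead when
   scoring external cohorts.
4. **Evaluation.** EI classes and scores are compared with outcomes:
   Welch's t for group contrasts (drug-resistant vs sensitive lines, PD-L1,
   mutation burden), Pearson correlation against IC50 or tumor shrinkage,
   Kaplan–Meier/log-rank and multivariate Cox models for RFS/OS.

A synthetic-cohort generator with planted up/down genes and class-dependent
survival makes the whole pipeline testable end to end without any external
data.

## Worked example

```r
library(egfrimpact)

co  <- generate_cohort(synthetic_spec(seed = 7))   # 200 genes x 100 samples, 20 mutant
sig <- derive_signature(co$matrix, co$annotation, seed = 7)
sig
#> EGFR signature: 3 up, 3 down
#>   up:  G0004, G0008, G0009
#>   down:G0017, G0019, ALK

sc  <- score_cohort(co$matrix, truth_signature(co))
roc <- calibrate_threshold(sc, co$annotation$egfr_status == "hotspot_mutant")
roc
#> ROC calibration: AUC 1.000, threshold 2.143 (Youden J 1.000), 20 pos / 80 neg

cls <- classify_impact(sc, roc$threshold)
head(cls, 3)
#> # A tibble: 3 x 6
#>   sample_id es_up es_down impact_score ei_class threshold
#>   <chr>     <dbl>   <dbl>        <dbl> <fct>        <dbl>
#> 1 S001      0.501  -0.481         2.89 EI_H          2.14
#> 2 S002      0.501  -0.497         2.99 EI_H          2.14
#> 3 S003      0.501  -0.499         3.00 EI_H          2.14

table(cls$ei_class, co$annotation$egfr_status)
#>        hotspot_mutant wild_type
#>   EI_H             20         0
#>   EI_L              0        80
```

The planted mutant samples activate the up-signature, so their enrichment
ratio sits well above the wild-type background; the ROC sweep separates
the classes perfectly here and places the cutoff (2.14) between the two
score clouds. Survival follows the same grammar:

```r
dat <- dplyr::left_join(cls, co$annotation, by = "sample_id")
km  <- km_logrank(dat$rfs_time, dat$rfs_event, dat$ei_class, endpoint = "RFS")
km
#> RFS: log-rank chi-square 1.057, p = 0.304 (n = 20 / 80)
autoplot(km)
```

(The planted EI-L hazard is twice the EI-H hazard; at 20/80 samples this
single cohort is underpowered, which is why the power analyses in the test
suite use larger, balanced cohorts.)

Results are plain tibbles / lightweight S3 objects with `tidy()`,
`glance()` and `autoplot()` methods, so they drop straight into dplyr and
ggplot2 pipelines. A command-line front end (`exec/egfr-impact`, installed
to `exec/` in the package library) exposes the same steps as
`simulate`, `deg`, `derive-signature`, `ssgsea`, `score`, `calibrate`
and `evaluate` subcommands over TSV/GMT files.

## Limitations

- ssGSEA scores are cohort-range-normalized by default, so a sample's score
  depends on the cohort it is scored with; use `normalize = FALSE` for
  cohort-independent scores (documented trade-offs in the vignette).
- The quartile-based importance selection retains at most ~25% of the
  nonzero-importance DEGs by construction; on cohorts where nearly all DEGs
  are true signal, the derived signature is therefore a small subset of it
  (see the vignette's discussion of the synthetic benchmarks).
- Log-rank is implemented for two groups; the Cox interface takes any
  covariate table but fits proportional hazards without diagnostics.
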