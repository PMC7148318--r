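Package: egfrimpact
Title: EGFR Impact Scoring of Lung Adenocarcinoma Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives paired up/down EGFR transcriptomic signatures from an
    EGFR mutant versus wild-type expression cohort (moderated t-statistic
    differential expression followed by random-forest variable-importance
    selection), scores individual samples by single-sample gene set
    enrichment analysis (ssGSEA), combines the two enrichment scores into
    the EGFR impact score (ES_up + 1)/(ES_down + 1), calibrates an
    EI-H/EI-L classification threshold by ROC analysis (Youden index), and
    evaluates the resulting classes against drug response and survival
    outcomes (Welch t, Pearson correlation, Kaplan-Meier/log-rank, Cox
    proportional hazards). Includes a synthetic-cohort generator with
    planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
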