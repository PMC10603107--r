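Package: exoscreen
Title: Extracellular Vesicle Protein Biomarker Screening and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovery and evaluation of extracellular-vesicle (EV) surface
    protein biomarkers for early cancer detection. Implements a replicate-aware
    presence/absence filtering cascade that reduces label-free proteomic
    abundance tables to a ranked list of candidate transmembrane EV proteins
    shared between a healthy tissue lineage and its derived carcinoma;
    single-marker receiver operating characteristic (ROC) statistics including
    kernel-smoothed ROC curves and the ROC arc-length statistic for flagging
    non-monotone markers; exhaustive logistic-regression subset search with
    Akaike Information Criterion (AIC) selection for multi-marker panels; and
    screening performance measures (Youden-index cutoffs, sensitivity at a
    forced specificity, positive predictive value at a population prevalence).
    A synthetic-data module generates study-shaped proteome tables and
    case/control marker panels with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
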