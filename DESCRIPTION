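Package: mqtrans
Title: Dark Biomarker Discovery via Transcription-Factor Regression Residuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects "dark" biomarkers: genes that are non-differentially
    expressed between two cohorts (for example metastatic versus primary
    tumours) yet show differential transcription regulation.  Per-gene linear
    models predict each mRNA's expression from transcription-factor (TF)
    expression over a primary-tumour training set; the residual of the model
    in a query sample (the mqTrans value, predicted minus observed
    expression) quantifies regulatory change relative to the training cohort.
    Genes with expression-space p > alpha but residual-space p < alpha are
    flagged as dark biomarkers.  Includes cohort readers for series-matrix
    style tables, TF registry and platform-annotation handling, model
    filtering by training Pearson correlation, cross-dataset intersection,
    training-size robustness scans, strand-aware lncRNA interval overlap
    screening, and a synthetic regulatory-cohort generator with ground-truth
    gene classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
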