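# mqtrans — dark biomarkers from TF-regression residuals

Differential-expression screens discard genes whose mean expression does not
move between conditions.  `mqtrans` looks exactly there.  For every mRNA it
fits, on a primary-tumour training cohort, a linear regression of the gene's
expression on transcription-factor (TF) expressions; the residual of that
model in a query sample — predicted minus observed expression, the *mqTrans
value* — quantifies how far the gene has drifted from the regulatory
relationship learned on the training cohort.  A **dark biomarker** is a gene
that is non-differential in expression space (`p_orig > 0.05`) but
differential in residual space (`p_mq < 0.05`) between metastatic and
primary samples:

    y_hat_g(s) = b0_g + sum_j b_jg * x_j(s)        (TF regression, trained on primary)
    m_g(s)     = y_hat_g(s) - y_g(s)               (mqTrans residual)
    dark(g)    = p_orig(g) > alpha  AND  p_mq(g) < alpha

The package is aimed at transcriptomics analysts working with cohort
expression matrices (microarray or bulk RNA-seq on a log scale) who want a
tested, reproducible implementation of this residual-based screen: cohort
readers and label curation, per-gene model fitting with predictor
pre-selection and a training-PCC retention gate, dual-space t-tests,
cross-dataset intersection, training-size robustness scans, strand-aware
lncRNA overlap screening, and a synthetic cohort generator with ground-truth
gene classes that makes every stage testable offline.

## Worked example

The `analysis/` scripts run the whole study on synthetic cohorts.  Three
cohorts (400 primary + 60 metastatic samples; 100 TFs of which 10 shift in
metastatic samples; 300 genes of which 30 are dark, 30 bright, 30 passenger,
210 null) share one regulatory program:

```sh
Rscript analysis/01_simulate.R 1     # write cohorts under results/cohorts/
Rscript analysis/02_fit_models.R 1   # fit + filter models on cohort 1
Rscript analysis/03_detect.R 1       # mqTrans, dual-space tests, intersection
Rscript analysis/04_robustness.R 1   # retrain at 50/40/20% of primary samples
Rscript analysis/05_overlap.R 1      # lncRNA overlap screen on bundled loci
```

`02_fit_models.R` prints the feature funnel:

```
Feature partition: 100 TF, 300 mRNA, 0 unmapped
Split: 240 primary training samples, 220 test samples
Fitted 300 models; 300 retained at training PCC > 0.5 (median PCC 0.711)
```

240 is 60% of the 400 primary samples; the remaining 160 primary plus all 60
metastatic samples form the test set.  `03_detect.R` then reports, per
cohort, how many genes pass the dual-space rule, and intersects the three
dark sets:

```
Per-cohort dark sets: cohort1=40, cohort2=41, cohort3=30
Intersection across the three cohorts: 23 features
  dark      class: 23/30 in the intersection
  bright    class: 0/30 in the intersection
  passenger class: 0/30 in the intersection
  null      class: 0/210 in the intersection
Intersection recall on injected dark genes: 0.77
```

All 23 intersected features are injected dark genes — no bright
(expression-shifted), passenger (regulator-shifted but uncompensated) or
null gene survives the triple intersection.  Recall below ~0.86 is expected:
a truly dark gene's expression p-value is uniform, so the `p_orig > 0.05`
clause alone survives three cohorts with probability 0.95³.

`04_robustness.R` shows the screen degrading gracefully with training size
(28/30, 28/30 and 23/30 injected dark genes recovered at 50%, 40% and 20% of
primary samples), and `05_overlap.R` counts sense/antisense lncRNA overlaps
per gene locus against a synthetic catalogue.

The same machinery is available programmatically:

```r
library(mqtrans)
co  <- generate_reference_cohort(seed = 1)
sp  <- split_train_test(co$labels, fraction = 0.6, seed = 1)
mod <- filter_models(fit_gene_models(co$expression, co$program$tf_ids,
                                     co$program$gene_ids, sample_ids = sp$train))
mq  <- compute_mqtrans(mod, co$expression[, sp$test])
tab <- detect_dark(co$expression[, sp$test], mq, co$labels)
head(dark_features(tab))
```

Real cohorts enter through `read_expression_matrix()` (features × samples
TSV), `read_sample_metadata()` + `curate_labels()` (TNM M parameter,
metastasis date, diagnosis keywords), `read_platform_annotation()` +
`read_tf_registry()` + `partition_features()` (probe → symbol maps with
"///" multi-symbol entries, TF symbol lists), and `run_discovery()`
orchestrates everything from a single YAML/list config.

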