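#!/usr/bin/env Rscript
# Fit the per-gene TF regressions on the training cohort's primary training
# split, filter them by training PCC, and write the model tables.  Reports
# the feature funnel (TF/mRNA partition -> fitted -> retained).
#
# Usage: Rscript analysis/02_fit_models.R [seed]   (run 01_simulate.R first)

library(mqtrans)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

cohort_dir <- "results/cohorts/cohort1"
if (!file.exists(file.path(cohort_dir, "expression.tsv"))) {
  stop("cohort files not found; run analysis/01_simulate.R first")
}

expr <- read_expression_matrix(file.path(cohort_dir, "expression.tsv"))
labels <- curate_labels(read_sample_metadata(file.path(cohort_dir, "metadata.tsv")))
registry <- read_tf_registry(file.path(cohort_dir, "tf_registry.txt"))
annotation <- read_platform_annotation(file.path(cohort_dir, "annotation.tsv"))
part <- partition_features(annotation, registry)

tf <- names(part$feature_class)[part$feature_class == "TF"]
mrna <- names(part$feature_class)[part$feature_class == "mRNA"]
cat(sprintf("Feature partition: %d TF, %d mRNA, %d unmapped\n",
            length(tf), length(mrna),
            sum(part$feature_class == "unmapped")))

sp <- split_train_test(labels, 0.6, seed)
cat(sprintf("Split: %d primary training samples, %d test samples\n",
            length(sp$train), length(sp$test)))

models <- fit_gene_models(expr, tf, mrna, sample_ids = sp$train,
                          feature_symbols = part$probe_to_symbols)
retained <- filter_models(models, 0.5)
cat(sprintf("Fitted %d models; %d retained at training PCC > 0.5 (median PCC %.3f)\n",
            length(models$targets), length(retained$targets),
            stats::median(retained$training_pcc)))

dir.create("results/models", recursive = TRUE, showWarnings = FALSE)
write_model_tables(retained,
                   "results/models/model_weights.tsv",
                   "results/models/model_summary.tsv")
cat("Model tables written under results/models/\n")
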