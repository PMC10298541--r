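#!/usr/bin/env Rscript
# Training-size robustness: retrain the models on 50%, 40% and 20% of the
# primary samples (sub-sampled from the main 60% training pool, test set held
# fixed) and tabulate which dark biomarkers survive smaller training cohorts.
#
# Usage: Rscript analysis/04_robustness.R [seed]   (run 01_simulate.R first)

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
part <- partition_features(
  read_platform_annotation(file.path(cohort_dir, "annotation.tsv")), registry)
tf <- names(part$feature_class)[part$feature_class == "TF"]
mrna <- names(part$feature_class)[part$feature_class == "mRNA"]

sp <- split_train_test(labels, 0.6, seed)
main_models <- filter_models(fit_gene_models(expr, tf, mrna, sample_ids = sp$train))
main_mq <- compute_mqtrans(main_models, expr[, sp$test, drop = FALSE])
main_dark <- dark_features(detect_dark(expr[, sp$test, drop = FALSE], main_mq, labels))
cat(sprintf("Main run (60%% of primary samples): %d dark biomarkers\n",
            length(main_dark)))

scan <- robustness_scan(expr, labels, train_pool = sp$train, fixed_test = sp$test,
                        predictors = tf, targets = mrna,
                        fractions = c(0.5, 0.4, 0.2),
                        main_fraction = 0.6, seed = seed)
tab <- robustness_overlap_table(scan, main_dark)
print(tab[, c("fraction", "n_train", "n_dark", "n_overlap_main")], row.names = FALSE)

truth <- utils::read.delim(file.path(cohort_dir, "truth.tsv"))
dark_genes <- truth$feature[truth$class == "dark"]
for (entry in scan) {
  cat(sprintf("  fraction %.1f: %d/%d injected dark genes recovered\n",
              entry$fraction, sum(dark_genes %in% entry$dark), length(dark_genes)))
}

dir.create("results/robustness", recursive = TRUE, showWarnings = FALSE)
utils::write.table(tab, "results/robustness/robustness_overlap.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Robustness table written under results/robustness/\n")
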