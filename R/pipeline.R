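#' Default discovery-run configuration
#'
#' Returns the full set of run parameters with the protocol's standard
#' values: 60% primary training fraction, robustness fractions 0.5/0.4/0.2,
#' dual-space significance thresholds 0.05/0.05, training-PCC retention
#' threshold 0.5, OLS estimator, pooled-variance t-test, shared-model
#' application to validation cohorts.
#'
#' @return Named list of defaults; override entries via the `config` argument
#'   of [run_discovery()].
#' @export
default_run_config <- function() {
  list(
    train_fraction = 0.6,
    robustness_fractions = c(0.5, 0.4, 0.2),
    alpha_orig = 0.05,
    alpha_mq = 0.05,
    pcc_threshold = 0.5,
    estimator = "ols",
    lasso_lambda = 0.01,
    n_top_tf = 16L,
    var_equal = TRUE,
    model_mode = "shared",   # "shared": apply training-cohort models everywhere;
                             # "retrain": refit per cohort on its own primary split
    figures = FALSE,
    seed = 1L
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_run_config(), config)
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$alpha_orig > 0, cfg$alpha_orig < 1,
            cfg$alpha_mq > 0, cfg$alpha_mq < 1,
            cfg$pcc_threshold > 0, cfg$pcc_threshold < 1)
  if (length(cfg$robustness_fractions) &&
      any(cfg$robustness_fractions <= 0 | cfg$robustness_fractions >= 1)) {
    stop("robustness fractions must lie in (0, 1)")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

load_cohort_inputs <- function(paths, keywords) {
  for (p in c(paths$expression, paths$metadata)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  expr <- read_expression_matrix(paths$expression)
  metadata <- read_sample_metadata(paths$metadata)
  labels <- curate_labels(metadata, keywords = keywords)
  list(expression = expr, labels = labels)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end dark-biomarker discovery workflow
#'
#' Orchestrates the complete chain: curate labels, partition features into TF
#' and mRNA classes, split the training cohort, fit and filter per-gene TF
#' regressions, compute mqTrans residuals, run the dual-space differential
#' tests in every cohort, intersect dark sets across cohorts, repeat the
#' detection at reduced training fractions, and (optionally) screen lncRNA
#' intervals overlapping the intersected dark genes.  All tables are written
#' as TSV under `config$out_dir` together with a JSON manifest recording the
#' configuration, seed and per-stage counts; a rerun with the same config and
#' seed reproduces every file byte for byte.
#'
#' @param config A named list or path to a YAML file.  Required entries:
#'   `cohorts` (named list; each element a list with `expression` and
#'   `metadata` paths), `training_cohort` (name of the cohort used for model
#'   fitting), `annotation` (platform annotation path), `tf_registry`
#'   (TF symbol list path), `out_dir`, `seed`.  Optional entries override
#'   [default_run_config()]; `genes_bed`/`lncrna_bed` enable the overlap
#'   screen; `metastasis_keywords` overrides the diagnosis lexicon.
#' @return Invisibly, a list with the in-memory results: per-cohort
#'   differential tables, dark sets, the intersection, robustness results,
#'   the retained model set, and the manifest.
#' @export
run_discovery <- function(config) {
  cfg <- read_run_config(config)
  for (key in c("cohorts", "training_cohort", "annotation", "tf_registry", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config is missing required entry: ", key)
  }
  if (!cfg$training_cohort %in% names(cfg$cohorts)) {
    stop("training_cohort '", cfg$training_cohort, "' is not among the cohorts")
  }
  if (!file.exists(cfg$tf_registry)) stop("TF registry file not found: ", cfg$tf_registry)
  if (!file.exists(cfg$annotation)) stop("annotation file not found: ", cfg$annotation)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  keywords <- if (is.null(cfg$metastasis_keywords)) default_metastasis_keywords()
              else cfg$metastasis_keywords

  registry <- read_tf_registry(cfg$tf_registry)
  annotation <- read_platform_annotation(cfg$annotation)
  partition <- partition_features(annotation, registry)
  log_stage("partition", sum(partition$feature_class == "TF"), " TF / ",
            sum(partition$feature_class == "mRNA"), " mRNA / ",
            sum(partition$feature_class == "unmapped"), " unmapped probes")

  cohorts <- lapply(cfg$cohorts, load_cohort_inputs, keywords = keywords)
  for (nm in names(cohorts)) {
    lab <- cohorts[[nm]]$labels
    log_stage("labels", nm, ": ", sum(lab$label == "primary"), " primary, ",
              sum(lab$label == "metastatic"), " metastatic, ",
              sum(lab$label == "excluded"), " excluded")
    write_tsv(lab, file.path(cfg$out_dir, paste0("labels_", nm, ".tsv")))
  }

  train_cohort <- cohorts[[cfg$training_cohort]]
  feat <- rownames(train_cohort$expression)
  tf_probes <- feat[partition$feature_class[feat] == "TF"]
  mrna_probes <- feat[partition$feature_class[feat] == "mRNA"]
  if (length(tf_probes) == 0L) stop("no TF features found in the training cohort")
  if (length(mrna_probes) == 0L) stop("no mRNA features found in the training cohort")

  split <- split_train_test(train_cohort$labels, cfg$train_fraction, cfg$seed)
  log_stage("split", length(split$train), " training / ", length(split$test),
            " test samples in ", cfg$training_cohort)

  fit_models <- function(sample_ids) {
    models <- fit_gene_models(
      train_cohort$expression, tf_probes, mrna_probes,
      sample_ids = sample_ids,
      method = cfg$estimator, lambda = cfg$lasso_lambda,
      n_top_tf = cfg$n_top_tf,
      feature_symbols = partition$probe_to_symbols
    )
    filter_models(models, cfg$pcc_threshold)
  }
  retained <- fit_models(split$train)
  log_stage("fit", length(mrna_probes), " candidate mRNAs -> ",
            length(retained$targets), " models retained at training PCC > ",
            cfg$pcc_threshold)
  write_model_tables(retained,
                     file.path(cfg$out_dir, "model_weights.tsv"),
                     file.path(cfg$out_dir, "model_summary.tsv"))

  detect_cohort <- function(nm, models) {
    cohort <- cohorts[[nm]]
    eval_samples <- if (nm == cfg$training_cohort) split$test else {
      cohort$labels$sample_id[cohort$labels$label != "excluded"]
    }
    data <- cohort$expression[, eval_samples, drop = FALSE]
    mq <- compute_mqtrans(models, data)
    write_expression_matrix(mq, file.path(cfg$out_dir, paste0("mqtrans_", nm, ".tsv")))
    diff_table <- detect_dark(data, mq, cohort$labels,
                              cfg$alpha_orig, cfg$alpha_mq, cfg$var_equal)
    write_tsv(diff_table, file.path(cfg$out_dir, paste0("differential_", nm, ".tsv")))
    diff_table
  }

  diff_tables <- list()
  dark_sets <- list()
  for (nm in names(cohorts)) {
    models_nm <- retained
    if (cfg$model_mode == "retrain" && nm != cfg$training_cohort) {
      local_split <- split_train_test(cohorts[[nm]]$labels, cfg$train_fraction, cfg$seed)
      local_train <- cohorts[[nm]]$expression
      models_nm <- filter_models(
        fit_gene_models(local_train, tf_probes, mrna_probes,
                        sample_ids = local_split$train,
                        method = cfg$estimator, lambda = cfg$lasso_lambda,
                        n_top_tf = cfg$n_top_tf,
                        feature_symbols = partition$probe_to_symbols),
        cfg$pcc_threshold)
    }
    diff_tables[[nm]] <- detect_cohort(nm, models_nm)
    dark_sets[[nm]] <- dark_features(diff_tables[[nm]])
    log_stage("detect", nm, ": ", length(dark_sets[[nm]]), " dark biomarkers")
  }

  venn <- intersect_dark(dark_sets)
  write_tsv(venn$sizes, file.path(cfg$out_dir, "venn_summary.tsv"))
  writeLines(sort(venn$intersection), file.path(cfg$out_dir, "dark_intersection.txt"))
  log_stage("intersect", length(venn$intersection),
            " dark biomarkers shared by all ", length(dark_sets), " cohorts")

  robustness <- NULL
  if (length(cfg$robustness_fractions)) {
    robustness <- robustness_scan(
      train_cohort$expression, train_cohort$labels,
      train_pool = split$train, fixed_test = split$test,
      predictors = tf_probes, targets = mrna_probes,
      fractions = cfg$robustness_fractions,
      main_fraction = cfg$train_fraction, seed = cfg$seed,
      pcc_threshold = cfg$pcc_threshold,
      alpha_orig = cfg$alpha_orig, alpha_mq = cfg$alpha_mq,
      var_equal = cfg$var_equal,
      method = cfg$estimator, lambda = cfg$lasso_lambda,
      n_top_tf = cfg$n_top_tf,
      feature_symbols = partition$probe_to_symbols
    )
    main_dark <- dark_sets[[cfg$training_cohort]]
    rob_table <- robustness_overlap_table(robustness, main_dark)
    write_tsv(rob_table, file.path(cfg$out_dir, "robustness_overlap.tsv"))
    for (entry in robustness) {
      log_stage("robustness", "fraction ", entry$fraction, ": ",
                entry$n_train, " training samples, ",
                length(entry$dark), " dark biomarkers")
    }
  }

  overlap_report <- NULL
  if (!is.null(cfg$genes_bed) && !is.null(cfg$lncrna_bed)) {
    genes_iv <- read_bed6(cfg$genes_bed)
    lncs_iv <- read_bed6(cfg$lncrna_bed)
    sel <- genes_iv$name %in% venn$intersection
    screened <- if (any(sel)) genes_iv[sel, , drop = FALSE] else genes_iv
    overlap_report <- screen_overlaps(screened, lncs_iv)
    write_overlap_report(overlap_report, file.path(cfg$out_dir, "lncrna_overlap.tsv"))
    log_stage("overlap", nrow(overlap_report), " gene loci screened against ",
              nrow(lncs_iv), " lncRNAs")
  }

  if (isTRUE(cfg$figures)) {
    plot_run_figures(cohorts, cfg, retained, diff_tables, venn, split)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mqtrans")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "cohorts")],
    cohort_paths = cfg$cohorts,
    counts = list(
      tf_features = length(tf_probes),
      mrna_features = length(mrna_probes),
      models_retained = length(retained$targets),
      dark_per_cohort = lapply(dark_sets, length),
      dark_intersection = length(venn$intersection)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    config = cfg, partition = partition, split = split, models = retained,
    diff_tables = diff_tables, dark_sets = dark_sets, venn = venn,
    robustness = robustness, overlap = overlap_report, manifest = manifest
  ))
}

# optional per-run figures: mqTrans/expression box plots of the intersected
# dark biomarkers plus per-cohort dark-set counts
plot_run_figures <- function(cohorts, cfg, models, diff_tables, venn, split) {
  fig_dir <- file.path(cfg$out_dir, "figures")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  top <- utils::head(sort(venn$intersection), 7L)
  if (length(top)) {
    nm <- cfg$training_cohort
    cohort <- cohorts[[nm]]
    eval_samples <- split$test
    data <- cohort$expression[, eval_samples, drop = FALSE]
    mq <- compute_mqtrans(models, data)
    lab <- cohort$labels[match(eval_samples, cohort$labels$sample_id), ]
    grp <- ifelse(lab$label == "metastatic", "M", "P")
    grDevices::png(file.path(fig_dir, "dark_boxplots.png"),
                   width = 1200, height = 500 * length(top), res = 120)
    graphics::par(mfrow = c(length(top), 2L), mar = c(3, 4, 2, 1))
    for (f in top) {
      graphics::boxplot(split(mq[f, ], grp), main = paste(f, "mqTrans"),
                        ylab = "predicted - observed (log2)")
      graphics::boxplot(split(data[f, ], grp), main = paste(f, "expression"),
                        ylab = "log2 intensity")
    }
    grDevices::dev.off()
  }
  sizes <- venn$sizes
  grDevices::png(file.path(fig_dir, "dark_set_sizes.png"),
                 width = 800, height = 600, res = 120)
  graphics::barplot(sizes$size, names.arg = sizes$set,
                    ylab = "dark biomarkers", las = 2)
  grDevices::dev.off()
  invisible(fig_dir)
}

#' Simulate cohorts and write them in the pipeline's input formats
#'
#' Generates one regulatory program and one or more cohorts sharing it
#' (emulating independent datasets drawn from the same biology), then writes
#' each cohort with [write_cohort()].  The files are directly consumable by
#' [run_discovery()].
#'
#' @param config Named list or YAML path.  Entries (all optional except
#'   `out_dir` and `seed`): `n_cohorts` (default 1), `n_primary`,
#'   `n_metastatic`, plus any [make_regulatory_program()] parameter
#'   (`n_tf`, `n_genes`, `class_counts`, `n_shifted_tf`, `delta`, ...).
#'   Defaults come from [reference_config()].
#' @return Invisibly, a list with the program and per-cohort directories.
#' @export
run_simulate <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(reference_config(), config)
  if (is.null(cfg$out_dir)) stop("config is missing required entry: out_dir")
  if (is.null(cfg$seed)) stop("config is missing required entry: seed")
  cfg$class_counts <- stats::setNames(as.integer(cfg$class_counts),
                                      names(cfg$class_counts))
  n_cohorts <- if (is.null(cfg$n_cohorts)) 1L else as.integer(cfg$n_cohorts)

  program <- make_regulatory_program(
    n_tf = cfg$n_tf, n_genes = cfg$n_genes, class_counts = cfg$class_counts,
    n_shifted_tf = cfg$n_shifted_tf, delta = cfg$delta,
    tf_mean = cfg$tf_mean, tf_sd = cfg$tf_sd, tf_cor = cfg$tf_cor,
    k_predictors = cfg$k_predictors, weight_range = cfg$weight_range,
    target_pcc = cfg$target_pcc, bright_shift = cfg$bright_shift,
    n_shifted_per_signal_gene = cfg$n_shifted_per_signal_gene,
    seed = as.integer(cfg$seed)
  )
  dirs <- character(n_cohorts)
  for (d in seq_len(n_cohorts)) {
    cohort <- generate_cohort(program, cfg$n_primary, cfg$n_metastatic,
                              seed = as.integer(cfg$seed) + 100000L * d,
                              sample_prefix = paste0("C", d))
    dirs[d] <- file.path(cfg$out_dir, paste0("cohort", d))
    write_cohort(cohort, dirs[d])
    log_stage("simulate", "cohort ", d, ": ",
              cfg$n_primary, " primary + ", cfg$n_metastatic,
              " metastatic samples written to ", dirs[d])
  }
  invisible(list(program = program, dirs = dirs))
}
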