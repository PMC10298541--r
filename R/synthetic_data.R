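#' Build a random TF-to-gene regulatory program
#'
#' Constructs the ground-truth generative model behind the synthetic cohorts:
#' a block of correlated TF expressions and, per gene, a sparse set of TF
#' predictors with signed weights, an intercept, and a noise SD calibrated so
#' that a regression trained on primary samples reaches a target training
#' PCC.  Genes carry one of four classes:
#'
#' * `null` — no shifted TF among its predictors; nothing changes between
#'   groups.
#' * `passenger` — regulators shift between groups and the gene simply tracks
#'   them: differentially expressed, but its residual against a
#'   primary-trained model stays centred at 0.
#' * `bright` — a TF-independent intercept shift in the metastatic group: the
#'   classic differentially expressed gene.
#' * `dark` — its shifted regulators are exactly compensated by an opposite
#'   intercept change in metastatic samples, so the marginal expression
#'   distribution is preserved while the residual mean moves by
#'   `sum(weights * delta * tf_sd)` over the shifted predictors.
#'
#' Dark and passenger genes receive `n_shifted_per_signal_gene` shifted TFs
#' among their predictors, with same-sign weights on those shifted TFs
#' (coordinated regulation), so the injected regulatory effect cannot cancel
#' itself; null and bright genes draw predictors from unshifted TFs only.
#'
#' @param n_tf Number of TF features.
#' @param n_genes Number of regulated mRNA features.
#' @param class_counts Named integer vector with entries `dark`, `bright`,
#'   `passenger`, `null` summing to `n_genes`.
#' @param n_shifted_tf Number of TFs whose group mean shifts; must be > 0
#'   whenever dark or passenger genes are requested.
#' @param delta Group mean shift of the shifted TFs, in TF-SD units.
#' @param tf_mean,tf_sd Mean and SD of TF expression (log2 scale).
#' @param tf_cor Exchangeable correlation among TFs.
#' @param k_predictors Candidate numbers of predictors per gene (sampled
#'   uniformly).
#' @param weight_range Range of absolute TF weights.
#' @param target_pcc Intended training PCC; the per-gene noise SD is set to
#'   `sqrt(signal_var * (1/target_pcc^2 - 1))`.
#' @param bright_shift Intercept shift of bright genes in metastatic samples,
#'   in units of that gene's noise SD.
#' @param n_shifted_per_signal_gene Shifted TFs per dark/passenger gene.
#' @param seed Integer seed; the program is fully determined by it.
#' @return Object of class `regulatory_program`.
#' @export
make_regulatory_program <- function(n_tf = 100L, n_genes = 300L,
                                    class_counts = c(dark = 30L, bright = 30L,
                                                     passenger = 30L, null = 210L),
                                    n_shifted_tf = 10L, delta = 1.0,
                                    tf_mean = 7, tf_sd = 1, tf_cor = 0.2,
                                    k_predictors = 3:8,
                                    weight_range = c(0.5, 1.5),
                                    target_pcc = 0.7, bright_shift = 0.8,
                                    n_shifted_per_signal_gene = 2L,
                                    seed) {
  stopifnot(n_tf >= 2L, n_genes >= 1L,
            all(c("dark", "bright", "passenger", "null") %in% names(class_counts)))
  class_counts <- class_counts[c("dark", "bright", "passenger", "null")]
  if (any(class_counts < 0L) || sum(class_counts) != n_genes) {
    stop("class counts must be non-negative and sum to n_genes")
  }
  if (n_shifted_tf == 0L && (class_counts[["dark"]] > 0L || class_counts[["passenger"]] > 0L)) {
    stop("dark or passenger genes requested but no TFs are shifted")
  }
  if (n_shifted_tf > 0L && n_shifted_tf < n_shifted_per_signal_gene) {
    stop("n_shifted_tf must be at least n_shifted_per_signal_gene")
  }
  stopifnot(target_pcc > 0, target_pcc < 1, tf_cor >= 0, tf_cor < 1)

  with_seed(seed, {
    tf_ids <- sprintf("TF_%04d_at", seq_len(n_tf))
    gene_ids <- sprintf("GENE_%04d_at", seq_len(n_genes))
    shifted <- if (n_shifted_tf > 0L) sort(sample.int(n_tf, n_shifted_tf)) else integer(0)
    unshifted <- setdiff(seq_len(n_tf), shifted)
    gene_class <- sample(rep(names(class_counts), class_counts))

    genes <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- if (length(k_predictors) == 1L) k_predictors else sample(k_predictors, 1L)
      cls <- gene_class[g]
      if (cls %in% c("dark", "passenger")) {
        k <- max(k, n_shifted_per_signal_gene + 1L)
        pred_shift <- sample(shifted, n_shifted_per_signal_gene)
        pred_rest <- sample(unshifted, k - n_shifted_per_signal_gene)
        pred <- c(pred_shift, pred_rest)
        signs <- c(rep(sample(c(-1, 1), 1L), n_shifted_per_signal_gene),
                   sample(c(-1, 1), k - n_shifted_per_signal_gene, replace = TRUE))
      } else {
        pred <- sample(unshifted, k)
        signs <- sample(c(-1, 1), k, replace = TRUE)
      }
      w <- signs * stats::runif(k, weight_range[1L], weight_range[2L])
      # exchangeable-cov signal variance: tf_sd^2 ((1-rho) sum w^2 + rho (sum w)^2)
      sig_var <- tf_sd^2 * ((1 - tf_cor) * sum(w^2) + tf_cor * sum(w)^2)
      noise_sd <- sqrt(sig_var * (1 / target_pcc^2 - 1))
      # keep the marginal gene mean near the TF scale
      intercept <- tf_mean - sum(w) * tf_mean + stats::rnorm(1L)
      genes[[g]] <- list(predictors = pred, weights = w,
                         intercept = intercept, noise_sd = noise_sd)
    }

    structure(list(
      n_tf = n_tf, n_genes = n_genes,
      tf_ids = tf_ids, gene_ids = gene_ids,
      tf_symbols = sprintf("SYNTF%04d", seq_len(n_tf)),
      gene_symbols = sprintf("SYNG%04d", seq_len(n_genes)),
      tf_mean = tf_mean, tf_sd = tf_sd, tf_cor = tf_cor,
      shifted_tfs = shifted, delta = delta,
      gene_class = stats::setNames(gene_class, gene_ids),
      genes = stats::setNames(genes, gene_ids),
      bright_shift = bright_shift,
      target_pcc = target_pcc,
      seed = seed
    ), class = "regulatory_program")
  })
}

#' Expected mqTrans mean shift per gene under a program
#'
#' Closed-form group difference (metastatic minus primary) of the residual
#' mean against a model trained on primary samples: `sum(weights * delta *
#' tf_sd)` over the gene's shifted predictors for dark genes (the intercept
#' compensation surfaces in residual space), 0 for every other class.
#'
#' @param program A `regulatory_program`.
#' @return Named numeric vector over genes.
#' @export
expected_mq_shift <- function(program) {
  stopifnot(inherits(program, "regulatory_program"))
  vapply(program$gene_ids, function(gid) {
    if (program$gene_class[[gid]] != "dark") return(0)
    gene <- program$genes[[gid]]
    sel <- gene$predictors %in% program$shifted_tfs
    sum(gene$weights[sel]) * program$delta * program$tf_sd
  }, numeric(1L))
}

#' Generate a synthetic primary/metastatic cohort
#'
#' Draws TF expression from the program's correlated Gaussian (metastatic
#' samples receive the group shift `delta` on the shifted TFs, in TF-SD
#' units), then each gene as intercept + weights x TFs + Gaussian noise with
#' the class-specific modification described in [make_regulatory_program()].
#' Fully deterministic under `seed`.
#'
#' @param program A `regulatory_program`.
#' @param n_primary,n_metastatic Group sizes, each >= 4.
#' @param seed Integer seed for the sample draw.
#' @param sample_prefix Prefix for sample IDs (useful when several cohorts
#'   share a program).
#' @return List of class `synthetic_cohort`: `expression` (TF + gene rows x
#'   samples), `labels` (curated annotation data frame), `truth` (list with
#'   `shifted_tfs`, `gene_class`, `expected_mq_shift`, `seed`), `annotation`
#'   (probe -> symbol table), `tf_registry`, and `program`.
#' @export
generate_cohort <- function(program, n_primary, n_metastatic, seed,
                            sample_prefix = "S") {
  stopifnot(inherits(program, "regulatory_program"))
  if (n_primary < 4L || n_metastatic < 4L) {
    stop("need at least 4 samples per group")
  }
  n <- n_primary + n_metastatic
  is_met <- c(rep(FALSE, n_primary), rep(TRUE, n_metastatic))
  sample_ids <- c(sprintf("%sP%04d", sample_prefix, seq_len(n_primary)),
                  sprintf("%sM%04d", sample_prefix, seq_len(n_metastatic)))

  expr <- with_seed(seed, {
    # exchangeable correlation via shared + idiosyncratic factors (exact)
    shared <- stats::rnorm(n)
    Z <- matrix(stats::rnorm(n * program$n_tf), nrow = n)
    tf_mat <- program$tf_mean + program$tf_sd *
      (sqrt(program$tf_cor) * shared + sqrt(1 - program$tf_cor) * Z)
    tf_mat[is_met, program$shifted_tfs] <- tf_mat[is_met, program$shifted_tfs] +
      program$delta * program$tf_sd

    gene_mat <- matrix(NA_real_, nrow = n, ncol = program$n_genes)
    mq_shift <- expected_mq_shift(program)
    for (g in seq_len(program$n_genes)) {
      gid <- program$gene_ids[g]
      gene <- program$genes[[gid]]
      base <- gene$intercept +
        tf_mat[, gene$predictors, drop = FALSE] %*% gene$weights +
        stats::rnorm(n, sd = gene$noise_sd)
      cls <- program$gene_class[[gid]]
      if (cls == "bright") {
        base[is_met] <- base[is_met] + program$bright_shift * gene$noise_sd
      } else if (cls == "dark") {
        base[is_met] <- base[is_met] - mq_shift[[gid]]
      }
      gene_mat[, g] <- base
    }
    out <- t(cbind(tf_mat, gene_mat))
    dimnames(out) <- list(c(program$tf_ids, program$gene_ids), sample_ids)
    out
  })

  metadata <- data.frame(
    sample_id = sample_ids,
    m_parameter = as.integer(is_met),
    metastasis_date = NA_character_,
    diagnosis = NA_character_,
    stringsAsFactors = FALSE
  )
  labels <- curate_labels(metadata)
  annotation <- data.frame(
    probe_id = c(program$tf_ids, program$gene_ids),
    gene_symbols = c(program$tf_symbols, program$gene_symbols),
    stringsAsFactors = FALSE
  )
  list(
    expression = expr,
    labels = labels,
    metadata = metadata,
    truth = list(
      shifted_tfs = program$tf_ids[program$shifted_tfs],
      gene_class = program$gene_class,
      expected_mq_shift = expected_mq_shift(program),
      seed = seed
    ),
    annotation = annotation,
    tf_registry = program$tf_symbols,
    program = program
  )
}

#' Reference synthetic study configuration
#'
#' The documented benchmark configuration used throughout the package's
#' validation: 100 TFs of which 10 shift by 1 TF-SD, 300 genes split 30 dark
#' / 30 bright / 30 passenger / 210 null, cohorts of 400 primary and 60
#' metastatic samples, per-gene noise calibrated for training PCC of about
#' 0.7, evaluated over seeds 1..20.
#'
#' @return Named list of generator parameters plus the evaluation `seeds`.
#' @export
reference_config <- function() {
  list(
    n_tf = 100L,
    n_shifted_tf = 10L,
    delta = 1.0,
    n_genes = 300L,
    class_counts = c(dark = 30L, bright = 30L, passenger = 30L, null = 210L),
    n_primary = 400L,
    n_metastatic = 60L,
    target_pcc = 0.7,
    tf_mean = 7, tf_sd = 1, tf_cor = 0.2,
    k_predictors = 3:8,
    weight_range = c(0.5, 1.5),
    bright_shift = 0.8,
    n_shifted_per_signal_gene = 2L,
    train_fraction = 0.6,
    n_top_tf = 16L,
    pcc_threshold = 0.5,
    alpha_orig = 0.05, alpha_mq = 0.05,
    seeds = 1:20
  )
}

#' Generate a cohort at the reference configuration
#'
#' @param seed Integer seed; the regulatory program uses `seed` and the
#'   sample draw uses a derived stream, so different seeds give independent
#'   replicates of the whole study.
#' @param n_primary,n_metastatic Optional overrides of the reference group
#'   sizes (e.g. for large-n checks of the class logic).
#' @return A `synthetic_cohort`, as from [generate_cohort()].
#' @export
generate_reference_cohort <- function(seed, n_primary = NULL, n_metastatic = NULL) {
  cfg <- reference_config()
  program <- make_regulatory_program(
    n_tf = cfg$n_tf, n_genes = cfg$n_genes, class_counts = cfg$class_counts,
    n_shifted_tf = cfg$n_shifted_tf, delta = cfg$delta,
    tf_mean = cfg$tf_mean, tf_sd = cfg$tf_sd, tf_cor = cfg$tf_cor,
    k_predictors = cfg$k_predictors, weight_range = cfg$weight_range,
    target_pcc = cfg$target_pcc, bright_shift = cfg$bright_shift,
    n_shifted_per_signal_gene = cfg$n_shifted_per_signal_gene,
    seed = seed
  )
  generate_cohort(program,
                  n_primary = if (is.null(n_primary)) cfg$n_primary else n_primary,
                  n_metastatic = if (is.null(n_metastatic)) cfg$n_metastatic else n_metastatic,
                  seed = seed + 100000L)
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Produces exactly the files the readers consume: `expression.tsv`
#' ([read_expression_matrix()]), `metadata.tsv` ([read_sample_metadata()]),
#' `annotation.tsv` ([read_platform_annotation()]), `tf_registry.txt`
#' ([read_tf_registry()]), plus `truth.tsv` (feature, class,
#' expected_mq_shift) carrying the generator ground truth.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    tf_registry = file.path(dir, "tf_registry.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(cohort$expression, paths$expression)
  utils::write.table(cohort$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$tf_registry, paths$tf_registry)
  truth_df <- data.frame(
    feature = names(cohort$truth$gene_class),
    class = unname(cohort$truth$gene_class),
    expected_mq_shift = unname(cohort$truth$expected_mq_shift),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
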