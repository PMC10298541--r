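#' Two-sample unpaired t-test with degenerate-group handling
#'
#' Student's pooled-variance test by default (`var_equal = TRUE`, df =
#' n_a + n_b - 2), matching the common default of the unpaired t-test in
#' scientific Python; set `var_equal = FALSE` for the Welch variant.
#' Degenerate inputs never error: two constant groups with equal values give
#' t = 0, p = 1; two constant groups with different values give the limiting
#' p = 0, with the situation recorded in `note`.
#'
#' @param a,b Numeric vectors, each of length >= 2 (NAs dropped).
#' @param var_equal Pooled-variance (TRUE) or Welch (FALSE) test.
#' @return List with `t`, `p`, `df`, and `note` (`"ok"`,
#'   `"degenerate_equal"` or `"degenerate_unequal"`).
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values")
  }
  eps <- 1e-12
  if (stats::sd(a) < eps && stats::sd(b) < eps) {
    if (abs(mean(a) - mean(b)) < eps) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  note = "degenerate_equal"))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2L, note = "degenerate_unequal"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), note = "ok")
}

#' Classify a feature as a dark biomarker from its two p-values
#'
#' A feature is dark iff it is non-differential in the original expression
#' space (`p_orig > alpha_orig`) but differential in mqTrans residual space
#' (`p_mq < alpha_mq`), both comparisons strict.  Missing p-values are never
#' dark.
#'
#' @param p_orig,p_mq P-values from the expression-space and mqTrans-space
#'   tests (vectorized).
#' @param alpha_orig,alpha_mq Significance thresholds, default 0.05 each.
#' @return Logical vector; `NA` p-values yield `FALSE`.
#' @export
classify_dark <- function(p_orig, p_mq, alpha_orig = 0.05, alpha_mq = 0.05) {
  ok <- !is.na(p_orig) & !is.na(p_mq)
  out <- rep(FALSE, length(ok))
  out[ok] <- p_orig[ok] > alpha_orig & p_mq[ok] < alpha_mq
  out
}

#' Dual-space differential testing and dark-biomarker calling
#'
#' For every retained mRNA feature (row of `mq`), runs the unpaired t-test
#' between metastatic and primary samples twice: on the original expression
#' values and on the mqTrans residuals.  A feature is flagged dark per
#' [classify_dark()].  Benjamini-Hochberg q-values are reported for both
#' spaces as supplementary columns but never gate the dark call, mirroring
#' the raw-threshold screening rule.
#'
#' @param data Expression matrix containing all features of `mq` and the
#'   tested samples.
#' @param mq mqTrans residual matrix from [compute_mqtrans()].
#' @param labels Label data frame from [curate_labels()]; only samples
#'   present in both matrices and labelled primary or metastatic are used.
#' @param alpha_orig,alpha_mq Thresholds for the dark rule.
#' @param var_equal Passed to [unpaired_ttest()].
#' @return Data frame with columns `feature`, `t_orig`, `p_orig`, `t_mq`,
#'   `p_mq`, `q_orig`, `q_mq`, `is_dark`, `reason` (`"ok"` or a degeneracy /
#'   missing-value code).
#' @export
detect_dark <- function(data, mq, labels, alpha_orig = 0.05, alpha_mq = 0.05,
                        var_equal = TRUE) {
  validate_expression_matrix(data)
  samples <- intersect(colnames(data), colnames(mq))
  lab <- labels[match(samples, labels$sample_id), , drop = FALSE]
  met <- samples[!is.na(lab$label) & lab$label == "metastatic"]
  pri <- samples[!is.na(lab$label) & lab$label == "primary"]
  if (length(met) < 2L) stop("fewer than 2 metastatic samples in the tested data")
  if (length(pri) < 2L) stop("fewer than 2 primary samples in the tested data")
  features <- rownames(mq)
  absent <- setdiff(features, rownames(data))
  if (length(absent)) stop("mqTrans feature missing from expression data: ", absent[1L])

  one_space <- function(m) {
    res <- lapply(features, function(f) {
      x <- m[f, met]
      y <- m[f, pri]
      if (sum(!is.na(x)) < 2L || sum(!is.na(y)) < 2L) {
        return(list(t = NA_real_, p = NA_real_, note = "missing_values"))
      }
      unpaired_ttest(x, y, var_equal = var_equal)
    })
    list(t = vapply(res, function(r) r$t, numeric(1L)),
         p = vapply(res, function(r) r$p, numeric(1L)),
         note = vapply(res, function(r) r$note, character(1L)))
  }
  orig <- one_space(data[features, c(met, pri), drop = FALSE])
  mqs <- one_space(mq[features, c(met, pri), drop = FALSE])

  is_dark <- classify_dark(orig$p, mqs$p, alpha_orig, alpha_mq)
  reason <- ifelse(orig$note != "ok", paste0("orig_", orig$note),
            ifelse(mqs$note != "ok", paste0("mq_", mqs$note), "ok"))
  data.frame(
    feature = features,
    t_orig = orig$t, p_orig = orig$p,
    t_mq = mqs$t, p_mq = mqs$p,
    q_orig = stats::p.adjust(orig$p, method = "BH"),
    q_mq = stats::p.adjust(mqs$p, method = "BH"),
    is_dark = is_dark,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Extract the dark-biomarker feature set from a differential table
#'
#' @param diff_table Data frame from [detect_dark()].
#' @return Character vector of dark feature IDs.
#' @export
dark_features <- function(diff_table) {
  as.character(diff_table$feature[diff_table$is_dark])
}

#' Intersect dark-biomarker sets across datasets
#'
#' @param sets Named list of character vectors (per-dataset dark features).
#' @return List with `intersection` (features dark in every dataset) and
#'   `sizes` (per-set and intersection cardinalities, Venn-style summary).
#' @export
intersect_dark <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  sets <- lapply(sets, as.character)
  inter <- Reduce(intersect, sets)
  sizes <- data.frame(
    set = c(names(sets), "intersection"),
    size = c(vapply(sets, length, integer(1L)), length(inter)),
    stringsAsFactors = FALSE
  )
  list(intersection = inter, sizes = sizes)
}

#' Robustness scan over reduced training fractions
#'
#' Re-runs the full model-training and dark-detection chain with training
#' sets sub-sampled from the main run's training pool, keeping the test set
#' fixed, to check which dark biomarkers survive smaller training cohorts.
#' Each fraction is interpreted against the total number of primary samples
#' (the same denominator as the main-run fraction): a scan fraction f draws
#' `floor(f * n_primary)` samples from `train_pool`.  A fraction equal to
#' `main_fraction` reproduces the main run exactly; larger fractions are
#' rejected.
#'
#' @param data Expression matrix covering train and test samples.
#' @param labels Label data frame ([curate_labels()]).
#' @param train_pool Training sample IDs of the main run.
#' @param fixed_test Test sample IDs of the main run (disjoint from
#'   `train_pool`).
#' @param predictors,targets Probe sets as in [fit_gene_models()].
#' @param fractions Numeric vector of scan fractions, each <= `main_fraction`.
#' @param main_fraction Fraction used by the main run (default 0.6).
#' @param seed Integer seed; each fraction draws from its own derived stream.
#' @param pcc_threshold,alpha_orig,alpha_mq,var_equal Detection parameters.
#' @param ... Further arguments to [fit_gene_models()].
#' @return Named list (one element per fraction as "f=<value>") with
#'   `train`, `n_train`, `dark` (feature set), and `diff_table`.
#' @export
robustness_scan <- function(data, labels, train_pool, fixed_test,
                            predictors, targets, fractions,
                            main_fraction = 0.6, seed,
                            pcc_threshold = 0.5,
                            alpha_orig = 0.05, alpha_mq = 0.05,
                            var_equal = TRUE, ...) {
  stopifnot(length(intersect(train_pool, fixed_test)) == 0L)
  if (any(fractions > main_fraction)) {
    stop("scan fraction exceeds the main-run training fraction")
  }
  n_primary <- sum(labels$label == "primary")
  out <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    n_sub <- floor(f * n_primary)
    if (n_sub < 2L) stop("fraction ", f, " yields fewer than 2 training samples")
    if (n_sub > length(train_pool)) {
      stop("fraction ", f, " requests more samples than the training pool holds")
    }
    sub <- with_seed(seed + i, sample(train_pool, n_sub))
    models <- fit_gene_models(data, predictors, targets, sample_ids = sub, ...)
    retained <- filter_models(models, pcc_threshold)
    mq <- compute_mqtrans(retained, data[, fixed_test, drop = FALSE])
    diff_table <- detect_dark(data[, fixed_test, drop = FALSE], mq, labels,
                              alpha_orig, alpha_mq, var_equal)
    out[[paste0("f=", format(f))]] <- list(
      fraction = f, train = sort(sub), n_train = n_sub,
      dark = dark_features(diff_table), diff_table = diff_table
    )
  }
  out
}

#' Tabulate a robustness scan against a main-run dark set
#'
#' @param scan Result of [robustness_scan()].
#' @param main_dark Character vector: the main run's dark features.
#' @return Data frame with one row per fraction: training size, dark-set
#'   size, overlap with the main run, and the overlapping features.
#' @export
robustness_overlap_table <- function(scan, main_dark) {
  rows <- lapply(scan, function(s) {
    shared <- intersect(s$dark, main_dark)
    data.frame(
      fraction = s$fraction,
      n_train = s$n_train,
      n_dark = length(s$dark),
      n_overlap_main = length(shared),
      overlap_features = paste(sort(shared), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
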