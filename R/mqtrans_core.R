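#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions
#' do not perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Split a cohort into a primary training set and a mixed test set
#'
#' Draws `floor(fraction * n_primary)` primary samples uniformly without
#' replacement as the training set; the test set is the remaining primary
#' samples plus all metastatic samples.  Excluded samples take part in
#' neither.  The draw is fully determined by `seed`.
#'
#' @param labels Data frame as returned by [curate_labels()] (columns
#'   `sample_id`, `label`).
#' @param fraction Fraction of primary samples used for training, in (0, 1).
#' @param seed Integer seed controlling the random draw.
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(labels, fraction = 0.6, seed) {
  stopifnot(is.data.frame(labels), all(c("sample_id", "label") %in% names(labels)))
  primary <- as.character(labels$sample_id[labels$label == "primary"])
  metastatic <- as.character(labels$sample_id[labels$label == "metastatic"])
  if (length(primary) < 2L) stop("need at least 2 primary samples to split")
  if (length(metastatic) < 1L) stop("need at least 1 metastatic sample")
  n_train <- floor(fraction * length(primary))
  if (n_train < 1L) stop("fraction ", fraction, " yields an empty training set")
  if (n_train >= length(primary)) {
    stop("fraction ", fraction, " leaves no primary samples for testing")
  }
  train <- with_seed(seed, sample(primary, n_train))
  list(train = train,
       test = c(setdiff(primary, train), metastatic))
}

# Minimum-norm least squares with intercept, shared across response columns.
# X: n x p predictor matrix, Y: n x m responses.  Centers both, solves the
# centered system through one SVD (rank-deficient designs get the
# minimum-norm weight vector, deterministically), and back-solves intercepts.
ols_min_norm <- function(X, Y) {
  xbar <- colMeans(X)
  ybar <- colMeans(Y)
  Xc <- sweep(X, 2L, xbar, "-")
  Yc <- sweep(Y, 2L, ybar, "-")
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) {
    W <- matrix(0, nrow = ncol(X), ncol = ncol(Y))
  } else {
    W <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], Yc) / sv$d[keep])
  }
  dimnames(W) <- list(colnames(X), colnames(Y))
  intercept <- ybar - drop(crossprod(W, xbar))
  names(intercept) <- colnames(Y)
  list(weights = W, intercept = intercept)
}

# Pearson correlation between fitted and observed values per response column;
# NA when either side is (numerically) constant, which marks the model
# unfittable downstream.
fitted_pcc <- function(fitted, observed) {
  vapply(seq_len(ncol(observed)), function(j) {
    f <- fitted[, j]
    y <- observed[, j]
    if (stats::sd(y) < 1e-12 || stats::sd(f) < 1e-12) return(NA_real_)
    stats::cor(f, y)
  }, numeric(1L))
}

#' Fit per-gene TF regression models
#'
#' For every target mRNA feature, fits a linear model of its expression on
#' the TF predictor expressions over the training samples.  The default
#' estimator is ordinary least squares with intercept; rank-deficient designs
#' (more predictors than samples) receive the minimum-norm solution, so fits
#' are deterministic and reproducible.  An L1-regularized estimator
#' (`method = "lasso"`, via glmnet at a fixed penalty) is available when
#' sparse TF weights are wanted.
#'
#' The training Pearson correlation (PCC) between fitted and observed target
#' values is stored per model; set `pcc_folds` to compute it by k-fold
#' cross-validation instead of on the training samples themselves.
#'
#' By default each model pre-selects its predictors by greedy forward
#' stepwise selection on the training samples: at each of `n_top_tf` steps
#' the TF most correlated with the current fitting residual is added and
#' partialled out.  This keeps each design well conditioned — regressing
#' every gene on the full TF panel interpolates the training data whenever
#' predictors outnumber samples, and even below that limit the estimation
#' noise on many irrelevant coefficients leaks group-level TF shifts into
#' every gene's residual.  Stepwise (rather than marginal-correlation)
#' screening matters under correlated TF panels, where a regulator's marginal
#' correlation can be masked by shared variation.  Set `n_top_tf = NULL` to
#' regress on the full predictor panel.
#'
#' If `feature_symbols` is supplied, any predictor probe sharing a gene
#' symbol with the target probe (the same TF measured by two probes) is
#' dropped from that target's model to avoid self-prediction; its weight is
#' reported as 0.
#'
#' Targets whose training expression is constant, or that carry missing
#' values, are marked unfittable (`training_pcc = NA`) and removed by
#' [filter_models()].  Predictors with missing training values are dropped
#' globally.
#'
#' @param train Expression matrix (features x samples) restricted to the
#'   training samples, or a full matrix plus `sample_ids`.
#' @param predictors Character vector of TF probe IDs (rows of `train`).
#' @param targets Character vector of mRNA probe IDs (rows of `train`),
#'   disjoint from `predictors`.
#' @param sample_ids Optional character vector selecting training columns.
#' @param method `"ols"` (default) or `"lasso"`.
#' @param lambda L1 penalty for `method = "lasso"`.
#' @param pcc_folds `NULL` for training-sample PCC, or an integer k >= 2 for
#'   k-fold cross-validated PCC.
#' @param n_top_tf Number of TFs pre-selected per target by forward stepwise
#'   selection (default 16); `NULL` uses every predictor.
#' @param feature_symbols Optional named list (probe -> character vector of
#'   gene symbols) used for self-prediction exclusion.
#' @param zero_tol Weights with magnitude at or below this count as zero.
#' @return An object of class `mqtrans_models`: predictor/target IDs, a
#'   predictors-x-targets weight matrix, per-target intercepts, training
#'   PCCs, non-zero weight counts, training residual SDs, and the training
#'   sample IDs.
#' @export
fit_gene_models <- function(train, predictors, targets, sample_ids = NULL,
                            method = c("ols", "lasso"), lambda = 0.01,
                            pcc_folds = NULL, n_top_tf = 16L,
                            feature_symbols = NULL, zero_tol = 1e-8) {
  method <- match.arg(method)
  validate_expression_matrix(train)
  if (!is.null(sample_ids)) {
    missing_s <- setdiff(sample_ids, colnames(train))
    if (length(missing_s)) stop("training sample not in matrix: ", missing_s[1L])
    # normalize to matrix column order so the fit is exactly invariant to the
    # order in which training samples are listed
    train <- train[, colnames(train) %in% sample_ids, drop = FALSE]
  }
  predictors <- as.character(predictors)
  targets <- as.character(targets)
  overlap <- intersect(predictors, targets)
  if (length(overlap)) stop("feature is both predictor and target: ", overlap[1L])
  missing_f <- setdiff(c(predictors, targets), rownames(train))
  if (length(missing_f)) stop("feature not in training matrix: ", missing_f[1L])
  if (ncol(train) < 2L) stop("need at least 2 training samples")

  # missing-data policy: predictors with any NA are unusable for every model;
  # targets with any NA are unfittable
  X_all <- t(train[predictors, , drop = FALSE])
  pred_ok <- predictors[colSums(is.na(X_all)) == 0L]
  if (length(pred_ok) == 0L) stop("no predictor is complete in the training samples")
  X <- X_all[, pred_ok, drop = FALSE]
  Y <- t(train[targets, , drop = FALSE])
  tgt_complete <- colSums(is.na(Y)) == 0L
  tgt_variable <- apply(Y, 2L, function(y) isTRUE(stats::sd(y[!is.na(y)]) > 1e-12))
  fittable <- tgt_complete & tgt_variable

  excl <- self_prediction_exclusions(pred_ok, targets, feature_symbols)

  # per-target predictor pre-selection by forward stepwise search, folded
  # into the exclusion sets
  if (!is.null(n_top_tf) && n_top_tf < length(pred_ok)) {
    for (j in which(fittable)) {
      t <- targets[j]
      usable <- setdiff(pred_ok, excl[[t]])
      keep <- usable[forward_select(X[, usable, drop = FALSE], Y[, j],
                                    min(n_top_tf, length(usable)))]
      excl[[t]] <- setdiff(pred_ok, keep)
    }
  }

  n <- nrow(X)
  p <- length(pred_ok)
  W <- matrix(0, nrow = p, ncol = length(targets),
              dimnames = list(pred_ok, targets))
  intercept <- stats::setNames(rep(NA_real_, length(targets)), targets)
  fitted <- matrix(NA_real_, nrow = n, ncol = length(targets),
                   dimnames = list(rownames(X), targets))

  fit_block <- function(Xb, Yb) {
    if (method == "ols") {
      ols_min_norm(Xb, Yb)
    } else {
      fit_lasso_block(Xb, Yb, lambda)
    }
  }

  plain <- which(fittable & !vapply(targets, function(t) length(excl[[t]]) > 0L, logical(1L)))
  if (length(plain)) {
    fit <- fit_block(X, Y[, plain, drop = FALSE])
    W[, plain] <- fit$weights
    intercept[plain] <- fit$intercept
    fitted[, plain] <- sweep(X %*% fit$weights, 2L, fit$intercept, "+")
  }
  special <- which(fittable & vapply(targets, function(t) length(excl[[t]]) > 0L, logical(1L)))
  for (j in special) {
    keep <- setdiff(pred_ok, excl[[targets[j]]])
    if (length(keep) == 0L) { fittable[j] <- FALSE; next }
    fit <- fit_block(X[, keep, drop = FALSE], Y[, j, drop = FALSE])
    W[keep, j] <- fit$weights[, 1L]
    intercept[j] <- fit$intercept[1L]
    fitted[, j] <- X[, keep, drop = FALSE] %*% fit$weights[, 1L] + fit$intercept[1L]
  }

  pcc <- stats::setNames(rep(NA_real_, length(targets)), targets)
  idx <- which(fittable)
  if (length(idx)) {
    if (is.null(pcc_folds)) {
      pcc[idx] <- fitted_pcc(fitted[, idx, drop = FALSE], Y[, idx, drop = FALSE])
    } else {
      pcc[idx] <- cv_pcc(X, Y[, idx, drop = FALSE], excl, targets[idx],
                         pcc_folds, fit_block)
    }
  }
  resid_sd <- stats::setNames(rep(NA_real_, length(targets)), targets)
  resid_sd[idx] <- apply(fitted[, idx, drop = FALSE] - Y[, idx, drop = FALSE], 2L, stats::sd)

  structure(list(
    predictors = pred_ok,
    targets = targets,
    weights = W,
    intercept = intercept,
    training_pcc = pcc,
    n_nonzero = colSums(abs(W) > zero_tol),
    train_resid_sd = resid_sd,
    fittable = stats::setNames(as.logical(fittable), targets),
    train_samples = rownames(X),
    method = method,
    zero_tol = zero_tol
  ), class = "mqtrans_models")
}

# Greedy forward stepwise predictor selection: at each step pick the column
# with the largest absolute partial correlation with the current residual,
# then orthogonalize the remaining columns and the residual against it
# (Gram-Schmidt).  Selection stops early once the best remaining partial
# correlation drops below the universal threshold sqrt(2 log(p) / n), the
# noise ceiling for the maximum of p null correlations, which makes the
# selection consistent: spurious predictors stop being picked as n grows.
# Deterministic; ties break toward the lower column index.  Always selects at
# least one column.  Returns selected column indices.
forward_select <- function(X, y, k) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  r <- y - mean(y)
  p <- ncol(Xc)
  n <- nrow(Xc)
  stop_pcor <- sqrt(2 * log(max(p, 2)) / n)
  sel <- integer(0)
  for (step in seq_len(min(k, p))) {
    rnorm2 <- sqrt(sum(r^2))
    if (rnorm2 < 1e-10) break
    cn <- sqrt(colSums(Xc^2))
    pcor <- abs(drop(crossprod(Xc, r))) / rnorm2
    pcor <- ifelse(cn > 1e-10, pcor / cn, -Inf)
    pcor[sel] <- -Inf
    j <- which.max(pcor)
    if (!is.finite(pcor[j])) break
    if (step > 1L && pcor[j] < stop_pcor) break
    sel <- c(sel, j)
    q <- Xc[, j] / cn[j]
    Xc <- Xc - q %*% crossprod(q, Xc)
    r <- r - q * drop(crossprod(q, r))
  }
  sort(sel)
}

# lasso over a block of responses at one fixed penalty
fit_lasso_block <- function(X, Y, lambda) {
  p <- ncol(X)
  W <- matrix(0, nrow = p, ncol = ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  intercept <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    fit <- glmnet::glmnet(X, Y[, j], alpha = 1, lambda = lambda,
                          standardize = TRUE, intercept = TRUE)
    W[, j] <- as.numeric(fit$beta)
    intercept[j] <- as.numeric(fit$a0)
  }
  names(intercept) <- colnames(Y)
  list(weights = W, intercept = intercept)
}

# k-fold cross-validated PCC between out-of-fold predictions and observations;
# honours each target's predictor subset (exclusions / pre-selection)
cv_pcc <- function(X, Y, excl, target_names, k, fit_block) {
  n <- nrow(X)
  k <- min(k, n)
  fold <- rep_len(seq_len(k), n)
  pred <- matrix(NA_real_, nrow = n, ncol = ncol(Y))
  for (j in seq_len(ncol(Y))) {
    usable <- setdiff(colnames(X), excl[[target_names[j]]])
    if (length(usable) == 0L) next
    Xj <- X[, usable, drop = FALSE]
    for (f in seq_len(k)) {
      hold <- fold == f
      fit <- fit_block(Xj[!hold, , drop = FALSE], Y[!hold, j, drop = FALSE])
      pred[hold, j] <- Xj[hold, , drop = FALSE] %*% fit$weights[, 1L] + fit$intercept[1L]
    }
  }
  fitted_pcc(pred, Y)
}

# map target -> predictor probes sharing any gene symbol with it
self_prediction_exclusions <- function(predictors, targets, feature_symbols) {
  out <- stats::setNames(vector("list", length(targets)), targets)
  if (is.null(feature_symbols)) return(out)
  for (t in targets) {
    t_sym <- feature_symbols[[t]]
    if (is.null(t_sym) || length(t_sym) == 0L) next
    hit <- vapply(predictors, function(p) {
      any(feature_symbols[[p]] %in% t_sym)
    }, logical(1L))
    out[[t]] <- predictors[hit]
  }
  out
}

#' Fit a single gene model
#'
#' Convenience wrapper around [fit_gene_models()] for one target.
#'
#' @inheritParams fit_gene_models
#' @param target One mRNA probe ID.
#' @return A list of class `gene_model`: `target_feature`,
#'   `predictor_features`, `weights`, `intercept`, `training_pcc`,
#'   `n_nonzero`, `fittable`.
#' @export
fit_gene_model <- function(train, predictors, target, ...) {
  stopifnot(length(target) == 1L)
  models <- fit_gene_models(train, predictors, target, ...)
  structure(list(
    target_feature = target,
    predictor_features = models$predictors,
    weights = models$weights[, 1L],
    intercept = unname(models$intercept[1L]),
    training_pcc = unname(models$training_pcc[1L]),
    n_nonzero = unname(models$n_nonzero[1L]),
    fittable = unname(models$fittable[1L])
  ), class = "gene_model")
}

#' Retain gene models by training PCC
#'
#' A model is retained iff its training PCC strictly exceeds the threshold
#' and it has at least one non-zero TF weight.  Unfittable models (PCC `NA`)
#' always fail the strict comparison and are dropped.
#'
#' @param models An `mqtrans_models` object.
#' @param pcc_threshold Retention threshold on the training PCC; models with
#'   PCC exactly equal to it are rejected.  Default 0.5.
#' @return The filtered `mqtrans_models` object.
#' @export
filter_models <- function(models, pcc_threshold = 0.5) {
  stopifnot(inherits(models, "mqtrans_models"))
  keep <- is.finite(models$training_pcc) &
    models$training_pcc > pcc_threshold &
    models$n_nonzero >= 1L &
    models$fittable
  subset_models(models, models$targets[keep])
}

subset_models <- function(models, targets) {
  idx <- match(targets, models$targets)
  stopifnot(!anyNA(idx))
  models$targets <- models$targets[idx]
  models$weights <- models$weights[, idx, drop = FALSE]
  models$intercept <- models$intercept[idx]
  models$training_pcc <- models$training_pcc[idx]
  models$n_nonzero <- models$n_nonzero[idx]
  models$train_resid_sd <- models$train_resid_sd[idx]
  models$fittable <- models$fittable[idx]
  models
}

#' @export
print.mqtrans_models <- function(x, ...) {
  cat("mqtrans model set:", length(x$targets), "targets,",
      length(x$predictors), "TF predictors,", x$method, "fit\n")
  ok <- is.finite(x$training_pcc)
  if (any(ok)) {
    cat(sprintf("  training PCC: median %.3f (range %.3f..%.3f), %d unfittable\n",
                stats::median(x$training_pcc[ok]), min(x$training_pcc[ok]),
                max(x$training_pcc[ok]), sum(!ok)))
  }
  invisible(x)
}

#' Compute mqTrans residuals for a sample set
#'
#' For every retained model and every sample, the mqTrans value is the
#' model-predicted expression (intercept + TF weights dotted with the
#' sample's TF expressions) minus the observed expression of the target —
#' i.e. predicted − real, in log2 units.  Each sample is scored
#' independently, so adding or permuting samples never changes other columns.
#'
#' @param models An `mqtrans_models` object (typically after
#'   [filter_models()]).
#' @param data Expression matrix containing every predictor and target
#'   feature of the model set.
#' @param standardize If `TRUE`, each feature's residuals are divided by that
#'   model's training residual SD (z-scoring against the training spread).
#'   Off by default; the raw residual is the canonical mqTrans value.
#' @return Numeric matrix, retained targets x samples, of residuals.
#' @export
compute_mqtrans <- function(models, data, standardize = FALSE) {
  stopifnot(inherits(models, "mqtrans_models"))
  validate_expression_matrix(data)
  needed <- c(models$predictors, models$targets)
  absent <- setdiff(needed, rownames(data))
  if (length(absent)) stop("feature required by models is missing from data: ", absent[1L])
  tf <- data[models$predictors, , drop = FALSE]
  predicted <- crossprod(models$weights, tf) + models$intercept
  mq <- predicted - data[models$targets, , drop = FALSE]
  rownames(mq) <- models$targets
  if (standardize) {
    sds <- models$train_resid_sd
    sds[!is.finite(sds) | sds < 1e-12] <- NA_real_
    mq <- mq / sds
  }
  mq
}

#' Serialize a model set to tab-separated tables
#'
#' Writes a long-format weights table (`target`, `predictor`, `weight`;
#' non-zero weights only) and a per-model summary (`target`, `intercept`,
#' `training_pcc`, `n_nonzero`).
#'
#' @param models An `mqtrans_models` object.
#' @param weights_path,summary_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_model_tables <- function(models, weights_path, summary_path) {
  stopifnot(inherits(models, "mqtrans_models"))
  nz <- which(abs(models$weights) > models$zero_tol, arr.ind = TRUE)
  long <- data.frame(
    target = models$targets[nz[, 2L]],
    predictor = models$predictors[nz[, 1L]],
    weight = models$weights[nz],
    stringsAsFactors = FALSE
  )
  long <- long[order(long$target, long$predictor), , drop = FALSE]
  utils::write.table(long, weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary_df <- data.frame(
    target = models$targets,
    intercept = unname(models$intercept),
    training_pcc = unname(models$training_pcc),
    n_nonzero = unname(models$n_nonzero),
    stringsAsFactors = FALSE
  )
  utils::write.table(summary_df, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(weights = weights_path, summary = summary_path))
}
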