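test_that("train/test split follows the counting rule and is seed-deterministic", {
  labels <- make_labels(10, 4)
  sp <- split_train_test(labels, 0.6, seed = 11)
  expect_length(sp$train, 6L)
  expect_length(sp$test, 8L)   # 4 remaining primary + 4 metastatic
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), labels$sample_id)
  expect_true(all(grepl("^P", sp$train)))
  expect_true(all(labels$sample_id[labels$label == "metastatic"] %in% sp$test))

  sp2 <- split_train_test(labels, 0.6, seed = 11)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(labels, 0.6, seed = 12)
  expect_false(setequal(sp$train, sp3$train))

  expect_error(split_train_test(labels, 1.0, seed = 1), "no primary")
  expect_error(split_train_test(labels, 0.01, seed = 1), "empty training")
})

test_that("excluded samples take part in neither split", {
  meta <- make_metadata(sample_id = sprintf("s%02d", 1:10),
                        m_parameter = c(0, 0, 0, 0, 0, 0, 1, 1, NA, NA))
  labels <- curate_labels(meta)
  sp <- split_train_test(labels, 0.5, seed = 5)
  expect_false(any(c("s09", "s10") %in% c(sp$train, sp$test)))
})

test_that("exactly representable targets are fit exactly", {
  # target equals one predictor column
  x <- tiny_matrix(features = c("tf1", "tf2", "g1"), samples = sprintf("s%d", 1:6), seed = 1)
  x["g1", ] <- x["tf1", ]
  m <- fit_gene_model(x, c("tf1", "tf2"), "g1")
  expect_equal(unname(m$weights["tf1"]), 1, tolerance = 1e-10)
  expect_equal(unname(m$weights["tf2"]), 0, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$training_pcc, 1, tolerance = 1e-10)

  # affine function of a single TF: weight 2, intercept 3, zero residuals
  y <- tiny_matrix(features = c("tf1", "g1"), samples = sprintf("s%d", 1:5), seed = 2)
  y["g1", ] <- 2 * y["tf1", ] + 3
  m2 <- fit_gene_model(y, "tf1", "g1")
  expect_equal(unname(m2$weights), 2, tolerance = 1e-10)
  expect_equal(m2$intercept, 3, tolerance = 1e-10)
  models <- fit_gene_models(y, "tf1", "g1")
  mq <- compute_mqtrans(models, y)
  expect_equal(max(abs(mq)), 0, tolerance = 1e-10)
})

test_that("constant targets are unfittable and predictors never overlap targets", {
  x <- tiny_matrix(features = c("tf1", "g1"), samples = sprintf("s%d", 1:5), seed = 3)
  x["g1", ] <- 4.2
  m <- fit_gene_model(x, "tf1", "g1")
  expect_false(m$fittable)
  expect_true(is.na(m$training_pcc))
  expect_error(fit_gene_models(x, c("tf1", "g1"), "g1"), "both predictor and target")
})

test_that("fits match the normal-equations oracle on random small instances", {
  for (case in 1:25) {
    n <- with_test_seed(case, sample(8:30, 1))
    p <- with_test_seed(case + 100, sample(1:6, 1))
    X <- with_test_seed(case + 200, matrix(rnorm(n * p), nrow = n))
    beta <- with_test_seed(case + 300, rnorm(p))
    y <- 1.5 + X %*% beta + with_test_seed(case + 400, rnorm(n, sd = 0.3))
    mat <- rbind(t(X), as.numeric(y))
    rownames(mat) <- c(sprintf("tf%d", seq_len(p)), "g")
    colnames(mat) <- sprintf("s%d", seq_len(n))
    m <- fit_gene_model(mat, sprintf("tf%d", seq_len(p)), "g", n_top_tf = NULL)
    oracle <- normal_equations_fit(X, y)
    expect_equal(unname(m$weights), unname(oracle$weights), tolerance = 1e-8)
    expect_equal(m$intercept, unname(oracle$intercept), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs get a deterministic minimum-norm solution", {
  # duplicated predictor column: OLS is non-unique, min-norm splits the weight
  n <- 12
  x1 <- with_test_seed(9, rnorm(n))
  mat <- rbind(tf1 = x1, tf2 = x1, g = 3 * x1 + 1)
  colnames(mat) <- sprintf("s%d", seq_len(n))
  m1 <- fit_gene_model(mat, c("tf1", "tf2"), "g", n_top_tf = NULL)
  expect_equal(unname(m1$weights), c(1.5, 1.5), tolerance = 1e-8)
  m2 <- fit_gene_model(mat, c("tf1", "tf2"), "g", n_top_tf = NULL)
  expect_identical(m1$weights, m2$weights)
})

test_that("adding noise to a target does not increase expected training PCC", {
  n <- 40
  X <- with_test_seed(21, matrix(rnorm(n * 3), nrow = n))
  y0 <- X %*% c(1, -1, 0.5)
  pccs <- vapply(1:10, function(s) {
    y <- y0 + with_test_seed(500 + s, rnorm(n, sd = 2))
    mat <- rbind(t(X), as.numeric(y))
    rownames(mat) <- c("tf1", "tf2", "tf3", "g")
    colnames(mat) <- sprintf("s%d", seq_len(n))
    fit_gene_model(mat, c("tf1", "tf2", "tf3"), "g")$training_pcc
  }, numeric(1))
  exact <- {
    mat <- rbind(t(X), as.numeric(y0))
    rownames(mat) <- c("tf1", "tf2", "tf3", "g")
    colnames(mat) <- sprintf("s%d", seq_len(n))
    fit_gene_model(mat, c("tf1", "tf2", "tf3"), "g")$training_pcc
  }
  expect_equal(exact, 1, tolerance = 1e-10)
  expect_true(mean(pccs) < 1)
  expect_true(all(pccs <= 1))
})

test_that("model filtering is strict at the threshold and monotone", {
  co <- small_cohort(31)
  sp <- split_train_test(co$labels, 0.6, 31)
  models <- fit_gene_models(co$expression, co$program$tf_ids,
                            co$program$gene_ids, sample_ids = sp$train)
  # strictness: force one model's PCC to sit exactly on the threshold
  models$training_pcc[1] <- 0.5
  kept <- filter_models(models, 0.5)
  expect_false(models$targets[1] %in% kept$targets)
  expect_true(all(kept$training_pcc > 0.5))
  expect_true(all(kept$n_nonzero >= 1))

  # monotone: raising the threshold never adds a model
  thresholds <- c(0.3, 0.5, 0.7, 0.9)
  sets <- lapply(thresholds, function(th) filter_models(models, th)$targets)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }

  # NaN/unfittable models never pass
  models$training_pcc[2] <- NaN
  expect_false(models$targets[2] %in% filter_models(models, 0.5)$targets)
})

test_that("mqTrans values follow the predicted-minus-observed arithmetic", {
  # hand-computed case: weights (1, -1), intercept 0.5, TFs (2, 1), observed 1
  mat <- matrix(c(2, 1, 1), ncol = 1,
                dimnames = list(c("tf1", "tf2", "g"), "s1"))
  models <- structure(list(
    predictors = c("tf1", "tf2"), targets = "g",
    weights = matrix(c(1, -1), ncol = 1, dimnames = list(c("tf1", "tf2"), "g")),
    intercept = c(g = 0.5), training_pcc = c(g = 0.9),
    n_nonzero = c(g = 2L), train_resid_sd = c(g = 1),
    fittable = c(g = TRUE), train_samples = "s0",
    method = "ols", zero_tol = 1e-8
  ), class = "mqtrans_models")
  mq <- compute_mqtrans(models, mat)
  expect_equal(unname(mq["g", "s1"]), 0.5)

  missing <- mat[c("tf1", "g"), , drop = FALSE]
  expect_error(compute_mqtrans(models, missing), "tf2")
})

test_that("mqTrans is sample-local: column permutations and extra samples", {
  co <- small_cohort(17)
  sp <- split_train_test(co$labels, 0.6, 17)
  models <- filter_models(fit_gene_models(
    co$expression, co$program$tf_ids, co$program$gene_ids,
    sample_ids = sp$train))
  test_data <- co$expression[, sp$test, drop = FALSE]
  mq <- compute_mqtrans(models, test_data)

  perm <- with_test_seed(4, sample(ncol(test_data)))
  mq_perm <- compute_mqtrans(models, test_data[, perm, drop = FALSE])
  expect_identical(mq_perm, mq[, perm, drop = FALSE])

  subset_mq <- compute_mqtrans(models, test_data[, 1:5, drop = FALSE])
  expect_identical(subset_mq, mq[, 1:5, drop = FALSE])
})

test_that("forward selection recovers sign-masked regulators", {
  # under an exchangeable TF correlation a negative-weight regulator can have
  # near-zero marginal correlation with its target; stepwise must still find it
  n <- 400
  rho <- 0.4
  with_test_seed(77, {
    shared <- rnorm(n)
    Z <- matrix(rnorm(n * 20), nrow = n)
    X <- sqrt(rho) * shared + sqrt(1 - rho) * Z
    # coefficient chosen so cov(X1, y) = 2 * 4 * rho - 3.2 = 0: fully masked
    y <- 2 * rowSums(X[, 2:5]) - 3.2 * X[, 1] + rnorm(n, sd = 0.5)
  })
  marginal_cor <- abs(cor(X[, 1], y))
  expect_lt(marginal_cor, 0.15)  # masked
  mat <- rbind(t(X), as.numeric(y))
  rownames(mat) <- c(sprintf("tf%02d", 1:20), "g")
  colnames(mat) <- sprintf("s%d", seq_len(n))
  m <- fit_gene_model(mat, sprintf("tf%02d", 1:20), "g", n_top_tf = 10)
  expect_lt(abs(unname(m$weights["tf01"]) + 3.2), 0.2)
})

test_that("self-prediction exclusion removes symbol-sharing predictors", {
  x <- tiny_matrix(features = c("tfA", "tfB", "g1"), samples = sprintf("s%d", 1:20), seed = 6)
  x["g1", ] <- x["tfA", ] + 0.1 * with_test_seed(8, rnorm(20))
  symbols <- list(tfA = "SOX9", tfB = "MYC", g1 = "SOX9")
  m <- fit_gene_model(x, c("tfA", "tfB"), "g1", feature_symbols = symbols)
  expect_equal(unname(m$weights["tfA"]), 0)
  m_free <- fit_gene_model(x, c("tfA", "tfB"), "g1")
  expect_gt(abs(unname(m_free$weights["tfA"])), 0.5)
})

test_that("lasso models keep at least one non-zero TF weight and can be serialized", {
  co <- small_cohort(23)
  sp <- split_train_test(co$labels, 0.6, 23)
  genes <- co$program$gene_ids[1:5]
  models <- fit_gene_models(co$expression, co$program$tf_ids, genes,
                            sample_ids = sp$train, method = "lasso", lambda = 0.05)
  expect_true(all(models$n_nonzero >= 1))

  wpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_model_tables(models, wpath, spath)
  long <- utils::read.delim(wpath)
  summ <- utils::read.delim(spath)
  expect_setequal(unique(long$target), genes[models$n_nonzero > 0])
  expect_equal(nrow(summ), 5L)
  expect_equal(summ$n_nonzero, unname(models$n_nonzero))
})

test_that("cross-validated PCC is lower than training PCC on noisy targets", {
  co <- small_cohort(41)
  sp <- split_train_test(co$labels, 0.6, 41)
  genes <- co$program$gene_ids[1:10]
  m_train <- fit_gene_models(co$expression, co$program$tf_ids, genes,
                             sample_ids = sp$train)
  m_cv <- fit_gene_models(co$expression, co$program$tf_ids, genes,
                          sample_ids = sp$train, pcc_folds = 5)
  expect_lt(mean(m_cv$training_pcc), mean(m_train$training_pcc))
})
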