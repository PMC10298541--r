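test_that("pooled t-test matches its closed form and handles degeneracy", {
  # pooled variance: sp2 = 1, se = sqrt(2/3), t = -3/se, df = 4
  res <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
  t_oracle <- -3 / sqrt(2 / 3)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(round(res$t, 4), -3.6742)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(t_oracle, 4), tolerance = 1e-10)

  same <- unpaired_ttest(c(2.5, 3.5, 1), c(1, 2.5, 3.5))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  const_eq <- unpaired_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(const_eq$t, 0)
  expect_equal(const_eq$p, 1)
  expect_equal(const_eq$note, "degenerate_equal")

  const_ne <- unpaired_ttest(c(2, 2), c(3, 3))
  expect_equal(const_ne$p, 0)
  expect_equal(const_ne$note, "degenerate_unequal")

  expect_error(unpaired_ttest(1, c(1, 2)), "at least 2")
})

test_that("t statistics are invariant to within-group permutation", {
  a <- with_test_seed(1, rnorm(9))
  b <- with_test_seed(2, rnorm(7, mean = 1))
  base <- unpaired_ttest(a, b)
  perm <- unpaired_ttest(with_test_seed(3, sample(a)), with_test_seed(4, sample(b)))
  expect_equal(perm$t, base$t, tolerance = 1e-12)
  expect_equal(perm$p, base$p, tolerance = 1e-12)
})

test_that("Welch variant differs from pooled under unequal variances", {
  a <- with_test_seed(5, rnorm(10, sd = 5))
  b <- with_test_seed(6, rnorm(30, sd = 0.5))
  pooled <- unpaired_ttest(a, b, var_equal = TRUE)
  welch <- unpaired_ttest(a, b, var_equal = FALSE)
  expect_false(isTRUE(all.equal(pooled$df, welch$df)))
})

test_that("the dark rule is a strict dual-threshold classification", {
  expect_true(classify_dark(0.7722, 0.0022))
  expect_false(classify_dark(0.01, 0.01))   # differential in expression space
  expect_false(classify_dark(0.50, 0.50))   # not differential in residual space
  expect_false(classify_dark(0.05, 0.01))   # boundary: p_orig must exceed alpha
  expect_false(classify_dark(0.50, 0.05))   # boundary: p_mq must undercut alpha
  expect_false(classify_dark(NA, 0.01))
  expect_false(classify_dark(0.5, NA))
  expect_equal(classify_dark(c(0.5, 0.01), c(0.01, 0.01)), c(TRUE, FALSE))
  # configurable thresholds
  expect_true(classify_dark(0.2, 0.08, alpha_orig = 0.1, alpha_mq = 0.1))
})

test_that("dark detection finds an injected dark gene and respects preconditions", {
  co <- small_cohort(101, n_primary = 200L, n_metastatic = 60L)
  sp <- split_train_test(co$labels, 0.6, 101)
  models <- filter_models(fit_gene_models(
    co$expression, co$program$tf_ids, co$program$gene_ids, sample_ids = sp$train))
  test_data <- co$expression[, sp$test, drop = FALSE]
  mq <- compute_mqtrans(models, test_data)
  tab <- detect_dark(test_data, mq, co$labels)

  cls <- co$truth$gene_class
  dark_genes <- names(cls)[cls == "dark"]
  shifts <- abs(co$truth$expected_mq_shift[dark_genes])
  # the strongest injected dark gene must be recovered
  strongest <- dark_genes[which.max(shifts)]
  expect_true(strongest %in% dark_features(tab))

  # no expression-significant feature is ever dark
  expect_false(any(tab$p_orig <= 0.05 & tab$is_dark, na.rm = TRUE))
  # q-value columns present but not gating
  expect_true(all(c("q_orig", "q_mq") %in% names(tab)))

  all_primary <- co$labels
  all_primary$label[all_primary$label == "metastatic"] <- "primary"
  expect_error(detect_dark(test_data, mq, all_primary), "metastatic")
})

test_that("degenerate features are non-dark with a reason code, not errors", {
  co <- small_cohort(55)
  sp <- split_train_test(co$labels, 0.6, 55)
  models <- filter_models(fit_gene_models(
    co$expression, co$program$tf_ids, co$program$gene_ids, sample_ids = sp$train))
  test_data <- co$expression[, sp$test, drop = FALSE]
  mq <- compute_mqtrans(models, test_data)
  flat <- models$targets[1]
  test_data[flat, ] <- 5.0   # constant in both groups in expression space
  tab <- detect_dark(test_data, mq, co$labels)
  row <- tab[tab$feature == flat, ]
  expect_equal(row$reason, "orig_degenerate_equal")
  expect_equal(row$p_orig, 1)
})

test_that("dark-set intersection follows set algebra and is monotone", {
  res <- intersect_dark(list(d1 = c("A", "B", "C"), d2 = c("B", "C"), d3 = "C"))
  expect_equal(res$intersection, "C")
  expect_equal(res$sizes$size, c(3L, 2L, 1L, 1L))

  same <- intersect_dark(list(a = c("x", "y"), b = c("x", "y")))
  expect_setequal(same$intersection, c("x", "y"))

  with_empty <- intersect_dark(list(a = c("x", "y"), b = character(0)))
  expect_length(with_empty$intersection, 0L)

  # adding a dataset never enlarges the intersection
  sets <- list(a = c("p", "q", "r"), b = c("q", "r", "s"), c = c("r", "s"))
  for (k in 2:3) {
    expect_true(all(intersect_dark(sets[1:k])$intersection %in%
                      intersect_dark(sets[1:(k - 1)])$intersection))
  }
})

test_that("robustness scan at the main fraction reproduces the main run", {
  co <- small_cohort(71, n_primary = 100L, n_metastatic = 30L)
  sp <- split_train_test(co$labels, 0.6, 71)
  tf <- co$program$tf_ids
  genes <- co$program$gene_ids
  models <- filter_models(fit_gene_models(co$expression, tf, genes, sample_ids = sp$train))
  mq <- compute_mqtrans(models, co$expression[, sp$test, drop = FALSE])
  main_tab <- detect_dark(co$expression[, sp$test, drop = FALSE], mq, co$labels)
  main_dark <- dark_features(main_tab)

  scan <- robustness_scan(co$expression, co$labels,
                          train_pool = sp$train, fixed_test = sp$test,
                          predictors = tf, targets = genes,
                          fractions = c(0.6, 0.4, 0.2), main_fraction = 0.6, seed = 71)
  expect_setequal(scan[["f=0.6"]]$dark, main_dark)
  expect_identical(scan[["f=0.6"]]$diff_table$p_mq, main_tab$p_mq)
  expect_equal(scan[["f=0.4"]]$n_train, floor(0.4 * 100))
  expect_equal(scan[["f=0.2"]]$n_train, floor(0.2 * 100))
  expect_true(all(scan[["f=0.4"]]$train %in% sp$train))

  tab <- robustness_overlap_table(scan, main_dark)
  expect_equal(tab$fraction, c(0.6, 0.4, 0.2))
  expect_equal(tab$n_overlap_main[1], length(main_dark))
  expect_true(all(tab$n_overlap_main <= tab$n_dark))

  expect_error(robustness_scan(co$expression, co$labels, sp$train, sp$test,
                               tf, genes, fractions = 0.8,
                               main_fraction = 0.6, seed = 1),
               "exceeds")
  expect_length(robustness_scan(co$expression, co$labels, sp$train, sp$test,
                                tf, genes, fractions = numeric(0),
                                main_fraction = 0.6, seed = 1), 0L)
})
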