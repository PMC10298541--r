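# Small in-code fixtures shared across test files.

# tiny labelled expression matrix: k TFs driving m genes, two groups
tiny_matrix <- function(features = c("f1", "f2"), samples = c("s1", "s2"),
                        values = NULL, seed = 42) {
  if (is.null(values)) {
    values <- with_test_seed(seed, matrix(stats::rnorm(length(features) * length(samples)),
                                          nrow = length(features)))
  }
  dimnames(values) <- list(features, samples)
  values
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# metadata data frame builder
make_metadata <- function(sample_id, m_parameter = NA, metastasis_date = NA,
                          diagnosis = NA) {
  data.frame(sample_id = sample_id,
             m_parameter = m_parameter,
             metastasis_date = metastasis_date,
             diagnosis = diagnosis,
             stringsAsFactors = FALSE)
}

# labels for n_p primary ("P...") and n_m metastatic ("M...") samples
make_labels <- function(n_p, n_m) {
  curate_labels(make_metadata(
    sample_id = c(sprintf("P%03d", seq_len(n_p)), sprintf("M%03d", seq_len(n_m))),
    m_parameter = c(rep(0L, n_p), rep(1L, n_m))
  ))
}

# a small fully-synthetic study: cohort generated at reduced size so module
# tests stay fast; shares the reference generator code path
small_cohort <- function(seed, n_tf = 30L, n_genes = 60L,
                         class_counts = c(dark = 8L, bright = 8L, passenger = 8L, null = 36L),
                         n_primary = 80L, n_metastatic = 24L, ...) {
  program <- make_regulatory_program(
    n_tf = n_tf, n_genes = n_genes, class_counts = class_counts,
    n_shifted_tf = 5L, delta = 1.0, seed = seed, ...
  )
  generate_cohort(program, n_primary, n_metastatic, seed = seed + 1000L)
}

# independent normal-equations solve (with intercept), the regression oracle
normal_equations_fit <- function(X, y) {
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  list(intercept = beta[1L], weights = beta[-1L])
}

# brute-force all-pairs overlap counting, the interval oracle
brute_force_overlaps <- function(genes, lncs) {
  t(vapply(seq_len(nrow(genes)), function(i) {
    rel <- vapply(seq_len(nrow(lncs)), function(j) {
      classify_overlap(genes[i, ], lncs[j, ])
    }, character(1L))
    c(sense = sum(rel == "sense"), antisense = sum(rel == "antisense"))
  }, c(sense = 0L, antisense = 0L)))
}

# random interval table over few chromosomes, including zero-width neighbours
random_intervals <- function(n, seed, span = 1000L) {
  with_test_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    width <- sample.int(60L, n, replace = TRUE) - 1L
    genomic_intervals(
      name = sprintf("iv%03d", seq_len(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = start,
      end = start + width,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}
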