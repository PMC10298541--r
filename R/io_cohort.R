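#' Read an expression matrix from a tab-separated table
#'
#' Reads a features-by-samples table of log2-scale expression intensities in
#' the series-matrix-like dialect: first column holds feature (probe) IDs,
#' the header row holds sample IDs, cells are tab-separated.  Row and column
#' order are preserved exactly as written.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix with feature IDs as rownames and sample IDs as
#'   colnames.  Missing cells (empty or `NA`) become `NA`.
#' @seealso [write_expression_matrix()] for the inverse operation.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("expression matrix file must have a header and at least one feature row: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID in ", path, ": ",
         sample_ids[duplicated(sample_ids)][1L])
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncell <- lengths(body)
  bad <- which(ncell != length(header))
  if (length(bad)) {
    stop("ragged row in ", path, " at line ", bad[1L] + 1L,
         ": expected ", length(header), " fields, found ", ncell[bad[1L]])
  }
  feature_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ID in ", path, ": ",
         feature_ids[duplicated(feature_ids)][1L])
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                   dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    cells[cells == "" | cells == "NA"] <- NA
    values[i, ] <- as.numeric(cells)
  }
  validate_expression_matrix(values)
  values
}

#' Write an expression matrix as a tab-separated table
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  # 17 significant digits give an exact double round-trip; "NA" for missing
  body <- apply(x, 1L, function(row) paste(
    ifelse(is.na(row), "NA", formatC(row, digits = 17, format = "g")),
    collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Validate expression-matrix invariants
#'
#' Checks that a matrix has unique feature and sample IDs on its dimnames and
#' that every non-missing value is finite.
#'
#' @param x Numeric matrix.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate feature ID: ", rownames(x)[duplicated(rownames(x))][1L])
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample ID: ", colnames(x)[duplicated(colnames(x))][1L])
  }
  if (any(is.infinite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Default diagnosis keywords indicating distant metastasis
#'
#' A small case-insensitive lexicon matched against free-text diagnosis
#' fields when no TNM M parameter or metastasis date is available.  The list
#' is a configuration default, not a clinical standard: extend it to match
#' the vocabulary of the metadata at hand.
#'
#' @return Character vector of lowercase keywords.
#' @export
default_metastasis_keywords <- function() {
  c("distant metasta", "liver metasta", "lung metasta", "bone metasta",
    "brain metasta", "peritoneal metasta", "metastatic")
}

#' Curate metastasis labels from sample metadata
#'
#' Assigns each sample one of three labels.  A sample is `metastatic` if its
#' TNM M parameter exceeds 0, if a metastasis date is recorded, or if its
#' diagnosis text matches a distant-metastasis keyword.  A sample with no
#' metastasis evidence and a missing M parameter is `excluded` (no usable
#' label); all remaining samples are `primary`.
#'
#' @param records Data frame with columns `sample_id`, `m_parameter`
#'   (non-negative integer or `NA`), `metastasis_date` (string or `NA`;
#'   any non-empty value counts as present), `diagnosis` (string or `NA`).
#' @param keywords Lowercase keywords matched case-insensitively against
#'   `diagnosis`; see [default_metastasis_keywords()].
#' @return Data frame: `sample_id`, `m_parameter`, `metastasis_date`,
#'   `diagnosis`, `label` (factor primary/metastatic/excluded), `reason`.
#' @export
curate_labels <- function(records, keywords = default_metastasis_keywords()) {
  stopifnot(is.data.frame(records), "sample_id" %in% names(records))
  if (anyDuplicated(records$sample_id)) {
    stop("duplicate sample_id: ",
         records$sample_id[duplicated(records$sample_id)][1L])
  }
  n <- nrow(records)
  m_par <- if ("m_parameter" %in% names(records)) {
    suppressWarnings(as.numeric(records$m_parameter))
  } else rep(NA_real_, n)
  date_chr <- if ("metastasis_date" %in% names(records)) {
    as.character(records$metastasis_date)
  } else rep(NA_character_, n)
  has_date <- !is.na(date_chr) & nzchar(trimws(date_chr))
  diag_chr <- if ("diagnosis" %in% names(records)) {
    tolower(as.character(records$diagnosis))
  } else rep(NA_character_, n)
  hits_kw <- rep(FALSE, n)
  for (kw in keywords) {
    hits_kw <- hits_kw | (!is.na(diag_chr) & grepl(kw, diag_chr, fixed = TRUE))
  }

  metastatic <- (!is.na(m_par) & m_par > 0) | has_date | hits_kw
  excluded <- !metastatic & is.na(m_par)
  label <- ifelse(metastatic, "metastatic", ifelse(excluded, "excluded", "primary"))
  reason <- ifelse(!is.na(m_par) & m_par > 0, "m_parameter>0",
            ifelse(has_date, "metastasis_date",
            ifelse(hits_kw, "diagnosis_keyword",
            ifelse(excluded, "no_metastasis_evidence", "m_parameter=0"))))
  data.frame(
    sample_id = as.character(records$sample_id),
    m_parameter = m_par,
    metastasis_date = ifelse(has_date, date_chr, NA_character_),
    diagnosis = if ("diagnosis" %in% names(records)) as.character(records$diagnosis) else NA_character_,
    label = factor(label, levels = c("primary", "metastatic", "excluded")),
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Read sample metadata in the pipeline's tab-separated dialect
#'
#' Columns: `sample_id`, `m_parameter`, `metastasis_date`, `diagnosis`.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with those columns (`NA` where empty).
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("sample_id", "m_parameter", "metastasis_date", "diagnosis")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample metadata ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read a TF registry (one gene symbol per line)
#'
#' @param path Path to a flat text file of TF gene symbols, one per line
#'   (AnimalTFDB-style list).  Blank lines are skipped.
#' @return Character vector of unique symbols.
#' @export
read_tf_registry <- function(path) {
  syms <- trimws(readLines(path))
  unique(syms[nzchar(syms)])
}

#' Read a platform annotation table mapping probes to gene symbols
#'
#' @param path TSV with header columns `probe_id` and `gene_symbols`, the
#'   latter a "///"-delimited symbol list (possibly empty), the GPL570
#'   convention for multi-gene probes.
#' @return Data frame with columns `probe_id`, `gene_symbols`.
#' @export
read_platform_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
  required <- c("probe_id", "gene_symbols")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("platform annotation ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df[required]
}

#' Partition probes into TF, mRNA and unmapped feature classes
#'
#' A probe is classified `TF` if any of its mapped gene symbols is in the TF
#' registry (TF takes priority for multi-symbol probes, so a probe partly
#' measuring a TF is never used as a regression target), `mRNA` if it maps to
#' at least one symbol but none is a registry TF, and `unmapped` if it has no
#' symbol.  Unmapped probes are never used as predictor or target.
#'
#' @param annotation Data frame with `probe_id` and `gene_symbols`
#'   ("///"-delimited, possibly empty) columns.
#' @param registry Character vector of TF gene symbols; must be non-empty.
#' @return List with `probe_to_symbols` (named list, probe -> character
#'   vector of symbols) and `feature_class` (named character vector, probe ->
#'   "TF"/"mRNA"/"unmapped").
#' @export
partition_features <- function(annotation, registry) {
  stopifnot(is.data.frame(annotation),
            all(c("probe_id", "gene_symbols") %in% names(annotation)))
  if (length(registry) == 0L) {
    stop("TF registry is empty: no feature can serve as a predictor")
  }
  probes <- as.character(annotation$probe_id)
  if (anyDuplicated(probes)) {
    stop("duplicate probe_id in annotation: ", probes[duplicated(probes)][1L])
  }
  sym_str <- as.character(annotation$gene_symbols)
  sym_str[is.na(sym_str)] <- ""
  symbols <- strsplit(sym_str, "///", fixed = TRUE)
  symbols <- lapply(symbols, function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
  names(symbols) <- probes
  is_tf <- vapply(symbols, function(s) any(s %in% registry), logical(1L))
  n_sym <- lengths(symbols)
  cls <- ifelse(is_tf, "TF", ifelse(n_sym > 0L, "mRNA", "unmapped"))
  names(cls) <- probes
  list(probe_to_symbols = symbols, feature_class = cls)
}
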