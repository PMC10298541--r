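#' Construct a genomic interval table
#'
#' Intervals are 1-based and inclusive on both ends (the convention of
#' printed gene loci tables); [read_bed6()] converts from BED's 0-based
#' half-open coordinates.
#'
#' @param name Feature names.
#' @param chrom Chromosome names (non-empty).
#' @param start,end Positive integer coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return Data frame with those five columns.
#' @export
genomic_intervals <- function(name, chrom, start, end, strand) {
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("name", "chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("interval with empty chromosome name")
  if (any(df$start < 1L | df$end < 1L)) stop("interval coordinates must be positive")
  if (any(df$start > df$end)) {
    bad <- which(df$start > df$end)[1L]
    stop("interval ", df$name[bad], " has start > end")
  }
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

#' Read a BED6 file as 1-based inclusive intervals
#'
#' BED coordinates are 0-based half-open; they are converted on read
#' (start + 1, end unchanged), so a BED record `chr1 99 200` becomes
#' chr1:100-200.
#'
#' @param path Path to a 6-column BED file (chrom, start, end, name, score,
#'   strand); comment/track/browser lines are skipped.
#' @return Interval data frame as from [genomic_intervals()].
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(genomic_intervals(character(0), character(0), integer(0), integer(0), character(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], " in ", path,
         ": expected >=6 tab-separated fields")
  }
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  strand <- vapply(fields, `[[`, character(1L), 6L)
  bad <- which(is.na(start0) | is.na(end0) | !(strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], " in ", path,
         ": non-numeric coordinates or invalid strand")
  }
  genomic_intervals(
    name = vapply(fields, `[[`, character(1L), 4L),
    chrom = vapply(fields, `[[`, character(1L), 1L),
    start = start0 + 1L,
    end = end0,
    strand = strand
  )
}

#' Classify the overlap relation between a gene and an lncRNA interval
#'
#' Complete and partial overlaps both count; a single shared base (inclusive
#' coordinates) is an overlap.  The relation is `sense` when the strands
#' match and `antisense` when they differ.
#'
#' @param gene,lnc Single-row interval data frames (or list-like with fields
#'   `chrom`, `start`, `end`, `strand`).
#' @return `"none"`, `"sense"` or `"antisense"`.
#' @export
classify_overlap <- function(gene, lnc) {
  if (gene$chrom != lnc$chrom) return("none")
  if (max(gene$start, lnc$start) > min(gene$end, lnc$end)) return("none")
  if (gene$strand == lnc$strand) "sense" else "antisense"
}

#' Screen lncRNAs overlapping gene loci, strand-aware
#'
#' Counts, per gene, the lncRNAs sharing at least one base with its locus on
#' the same (sense) and opposite (antisense) strand.  The overlap search is
#' interval-tree based (GenomicRanges); results are identical to an all-pairs
#' scan with [classify_overlap()] and invariant to input order.
#'
#' @param genes,lncs Interval data frames ([genomic_intervals()] /
#'   [read_bed6()]).
#' @return Data frame with one row per gene, in input order: `gene`, `chrom`,
#'   `start`, `end`, `strand`, `sense`, `antisense`, and `hits` (list column
#'   of per-hit data frames with `lncrna` and `relation`).
#' @export
screen_overlaps <- function(genes, lncs) {
  validate_intervals(genes)
  validate_intervals(lncs)
  n <- nrow(genes)
  sense <- integer(n)
  antisense <- integer(n)
  hits <- rep(list(data.frame(lncrna = character(0), relation = character(0),
                              stringsAsFactors = FALSE)), n)
  if (n > 0L && nrow(lncs) > 0L) {
    g <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end),
                                strand = genes$strand)
    l <- GenomicRanges::GRanges(lncs$chrom,
                                IRanges::IRanges(lncs$start, lncs$end),
                                strand = lncs$strand)
    ov <- GenomicRanges::findOverlaps(g, l, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    same <- genes$strand[qh] == lncs$strand[sh]
    sense <- tabulate(qh[same], nbins = n)
    antisense <- tabulate(qh[!same], nbins = n)
    for (i in unique(qh)) {
      sel <- qh == i
      hits[[i]] <- data.frame(
        lncrna = lncs$name[sh[sel]],
        relation = ifelse(same[sel], "sense", "antisense"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- data.frame(
    gene = genes$name, chrom = genes$chrom,
    start = genes$start, end = genes$end, strand = genes$strand,
    sense = as.integer(sense), antisense = as.integer(antisense),
    stringsAsFactors = FALSE
  )
  out$hits <- hits
  out
}

#' Write an overlap report as a TSV summary table
#'
#' Columns mirror a printed locus table: gene, chromosome, 1-based inclusive
#' start/end, strand, and sense/antisense overlap counts.  The per-hit list
#' column is flattened to a comma-separated `lncrnas` field.
#'
#' @param report Data frame from [screen_overlaps()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  flat <- report[, c("gene", "chrom", "start", "end", "strand", "sense", "antisense")]
  flat$lncrnas <- vapply(report$hits, function(h) {
    paste(paste0(h$lncrna, "(", substr(h$relation, 1L, 1L), ")"), collapse = ",")
  }, character(1L))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
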