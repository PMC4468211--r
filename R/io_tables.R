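#' Read a per-site tumor/pooled-normal count table
#'
#' The TSV schema carries, per genomic site, the tumor and pooled-normal
#' sequencing depth and mutant allele count (MAC). Positions are 1-based.
#' The mutant allele frequency MAF = MAC / depth is added for the tumor
#' (defined as 0 at zero depth).
#'
#' @param path TSV file with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_depth`, `tumor_mac`, `normal_depth`, `normal_mac`.
#' @return A tibble of site counts with an additional `tumor_maf` column.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("counts table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("chrom", "pos", "ref", "alt", "tumor_depth",
                      "tumor_mac", "normal_depth", "normal_mac"),
                 "counts table")
  validate_site_counts(x)
}

#' @rdname read_counts_table
#' @param counts Tibble in the count-table schema.
#' @export
validate_site_counts <- function(counts) {
  cnt_cols <- c("tumor_depth", "tumor_mac", "normal_depth", "normal_mac")
  for (cc in cnt_cols) {
    bad <- which(counts[[cc]] < 0)
    if (length(bad)) {
      abort(sprintf("record error at row %d: negative %s", bad[1], cc))
    }
  }
  bad <- which(counts$tumor_mac > counts$tumor_depth)
  if (length(bad)) {
    abort(sprintf("record error at row %d: tumor_mac > tumor_depth", bad[1]))
  }
  bad <- which(counts$normal_mac > counts$normal_depth)
  if (length(bad)) {
    abort(sprintf("record error at row %d: normal_mac > normal_depth", bad[1]))
  }
  if ("chrom" %in% names(counts)) {
    check_chrom_dialect(unique(counts$chrom), what = "counts table")
  }
  mutate(as_tibble(counts),
         tumor_maf = ifelse(.data$tumor_depth > 0,
                            .data$tumor_mac / .data$tumor_depth, 0))
}

#' @rdname read_counts_table
#' @export
write_counts_table <- function(counts, path) {
  keep <- intersect(c("chrom", "pos", "ref", "alt", "tumor_depth",
                      "tumor_mac", "normal_depth", "normal_mac"),
                    names(counts))
  readr::write_tsv(counts[keep], path, progress = FALSE)
  invisible(path)
}

#' Read a curated variant-position list
#'
#' Curated hotspot lists (an expert-curated "conservative" tier and a
#' broader, database-derived "less-conservative" tier) are consumed as
#' plain position tables with columns `chrom`, `pos`, `kind` (`SNV` or
#' `indel`) and `tier`; an optional `gene` column carries attribution.
#' Declared metadata counts, when given, are validated against the file.
#'
#' @param path TSV position list.
#' @param expected_snv,expected_indel,expected_genes Optional declared
#'   counts for the list; a mismatch is an error.
#' @return A tibble of positions with attributes `snv_count`,
#'   `indel_count` and `gene_count`.
#' @export
read_position_list <- function(path, expected_snv = NULL,
                               expected_indel = NULL, expected_genes = NULL) {
  if (!file.exists(path)) abort(sprintf("position list not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("chrom", "pos", "kind", "tier"), "position list")
  bad <- which(!x$kind %in% c("SNV", "indel"))
  if (length(bad)) {
    abort(sprintf("position list row %d: kind must be 'SNV' or 'indel'", bad[1]))
  }
  check_chrom_dialect(unique(x$chrom), what = "position list")
  x <- as_tibble(x)
  attr(x, "snv_count") <- sum(x$kind == "SNV")
  attr(x, "indel_count") <- sum(x$kind == "indel")
  attr(x, "gene_count") <- if ("gene" %in% names(x)) {
    length(unique(x$gene[!is.na(x$gene)]))
  } else NA_integer_
  for (chk in list(list(expected_snv, "snv_count", "SNV positions"),
                   list(expected_indel, "indel_count", "indel positions"),
                   list(expected_genes, "gene_count", "genes"))) {
    if (!is.null(chk[[1]]) && !identical(as.integer(chk[[1]]),
                                         as.integer(attr(x, chk[[2]])))) {
      abort(sprintf("position list declares %d %s but file contains %d",
                    as.integer(chk[[1]]), chk[[3]],
                    as.integer(attr(x, chk[[2]]))))
    }
  }
  x
}

#' Write copy-number segments in SEG format
#'
#' Standard tab-separated SEG output (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`), one row per segment, segment means
#' written to 4 decimal places. Segments must be sorted and
#' non-overlapping within each chromosome.
#'
#' @param segments Tibble with columns `chrom`, `start`, `end`,
#'   `n_windows`, `mean_cnr`.
#' @param sample_id Sample label for the ID column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, sample_id, path) {
  assert_columns(segments, c("chrom", "start", "end", "n_windows", "mean_cnr"),
                 "segments")
  if (nrow(segments)) {
    segments <- arrange(segments, .data$chrom, .data$start)
    ov <- segments |>
      group_by(.data$chrom) |>
      summarise(bad = any(.data$start[-1] <= .data$end[-n()]) %||% FALSE,
                .groups = "drop")
    if (nrow(segments) > 1 && any(ov$bad)) {
      abort("validation error: overlapping segments within a chromosome")
    }
  }
  out <- data.frame(
    ID = rep(sample_id, nrow(segments)),
    chrom = segments$chrom,
    loc.start = segments$start,
    loc.end = segments$end,
    num.mark = segments$n_windows,
    seg.mean = sprintf("%.4f", segments$mean_cnr)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(
    sample_id = x$ID, chrom = x$chrom,
    start = as.integer(x$loc.start), end = as.integer(x$loc.end),
    n_windows = as.integer(x$num.mark), mean_cnr = as.numeric(x$seg.mean)
  )
}
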