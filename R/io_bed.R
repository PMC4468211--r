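#' Read panel target regions from a BED file
#'
#' Reads BED3/BED4 capture-interval definitions and converts them to the
#' package's internal coordinate convention: 1-based, inclusive on both
#' ends. A BED record `(chrom, start, end)` in the 0-based half-open
#' dialect becomes the interval `start + 1 .. end`; the optional fourth
#' column is kept as the gene attribution of the region.
#'
#' @param path Path to a BED3 or BED4 file.
#' @param panel_version Free-text label attached to every region
#'   (capture design version).
#' @return A tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `gene_id` (`NA` when absent) and `panel_version`.
#'   Region length is `end - start + 1`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr12\t25398207\t25398318\tKRAS", bed)
#' read_bed(bed)  # 111-bp region chr12:25,398,208-25,398,318
#' @export
read_bed <- function(path, panel_version = NA_character_) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), panel_version = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                  idx[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is_wholenumber(start0) | !is_wholenumber(end0) | start0 < 0)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: non-integer or negative coordinate",
                  idx[bad[1]]))
  }
  bad <- which(end0 <= start0)
  if (length(bad)) {
    abort(sprintf("BED record error at line %d: end <= start", idx[bad[1]]))
  }
  gene <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))],
                                 character(1)), NA_character_)
  check_chrom_dialect(chrom, what = "BED file")
  tibble(
    chrom = chrom,
    start = as.integer(start0 + 1),
    end = as.integer(end0),
    gene_id = gene,
    panel_version = panel_version
  )
}

#' Write target regions to a BED file
#'
#' Inverse of [read_bed()]: internal 1-based inclusive intervals are
#' converted back to the 0-based half-open BED dialect, so that
#' `write_bed(read_bed(f))` reproduces coordinates exactly.
#'
#' @param regions Tibble with columns `chrom`, `start`, `end` and
#'   optionally `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  assert_columns(regions, c("chrom", "start", "end"), "regions")
  if (any(regions$start < 1 | regions$end < regions$start)) {
    abort("invalid region: need start >= 1 and end >= start")
  }
  has_gene <- "gene_id" %in% names(regions) && any(!is.na(regions$gene_id))
  out <- data.frame(
    chrom = regions$chrom,
    start = format(regions$start - 1L, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE)
  )
  if (has_gene) out$name <- ifelse(is.na(regions$gene_id), ".", regions$gene_id)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
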