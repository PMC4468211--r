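#' Write significant-SNV calls as a minimal VCF 4.2 file
#'
#' Serializes filtered calls with the site test statistics in INFO
#' (`PRAW`, `PBONF`, `MAF`, `MAC`, `LOG2OR`, `TIER`). `FILTER` is `PASS`
#' exactly when all four call filters pass; otherwise it lists the
#' failed filters (`pbonf_gt_alpha`, `maf_lt_min`, `mac_lt_5`,
#' `log2or_lt_4`, with thresholds taken from the call set's attributes
#' when non-default). Records are sorted by chromosome and position.
#'
#' @param calls Tibble of calls as produced by [test_sites()] +
#'   [filter_calls()]; must carry `chrom`, `pos`, `ref`, `alt`, `p_raw`,
#'   `p_bonf`, `tumor_maf`, `tumor_mac`, `log2_or` and the `pass_*` flag
#'   columns.
#' @param path Output path.
#' @param sample_id Label written in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(calls, path, sample_id = "TUMOR") {
  needed <- c("chrom", "pos", "ref", "alt", "p_raw", "p_bonf", "tumor_maf",
              "tumor_mac", "log2_or", "pass_pbonf", "pass_maf", "pass_mac",
              "pass_log2or")
  assert_columns(calls, needed, "calls")
  if (nrow(calls) && any(is.na(calls$ref) | is.na(calls$alt) |
                         !nzchar(calls$ref) | !nzchar(calls$alt))) {
    abort("record error: missing ref or alt allele")
  }
  calls <- arrange(as_tibble(calls), .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=panelscope %s", as.character(utils::packageVersion("panelscope"))),
    sprintf("##sample=%s", sample_id),
    "##INFO=<ID=PRAW,Number=1,Type=Float,Description=\"Raw one-sided LRT p-value, tumor vs pooled normal\">",
    "##INFO=<ID=PBONF,Number=1,Type=Float,Description=\"Bonferroni-adjusted p-value\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Tumor mutant allele frequency\">",
    "##INFO=<ID=MAC,Number=1,Type=Integer,Description=\"Tumor mutant allele count\">",
    "##INFO=<ID=LOG2OR,Number=1,Type=Float,Description=\"log2 odds ratio, tumor vs pooled normal\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Curated-list tier of the position\">",
    "##FILTER=<ID=pbonf_gt_alpha,Description=\"Bonferroni-adjusted p-value above threshold\">",
    "##FILTER=<ID=maf_lt_min,Description=\"Tumor MAF below threshold\">",
    "##FILTER=<ID=mac_lt_5,Description=\"Tumor mutant allele count below threshold\">",
    "##FILTER=<ID=log2or_lt_4,Description=\"log2 odds ratio below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (!nrow(calls)) {
    writeLines(header, path)
    return(invisible(path))
  }
  tier <- if ("tier" %in% names(calls)) as.character(calls$tier) else
    rep("none", nrow(calls))
  fails <- cbind(
    ifelse(calls$pass_pbonf, NA, "pbonf_gt_alpha"),
    ifelse(calls$pass_maf, NA, "maf_lt_min"),
    ifelse(calls$pass_mac, NA, "mac_lt_5"),
    ifelse(calls$pass_log2or, NA, "log2or_lt_4")
  )
  filt <- apply(fails, 1, function(f) {
    f <- f[!is.na(f)]
    if (!length(f)) "PASS" else paste(f, collapse = ";")
  })
  info <- sprintf("PRAW=%.6g;PBONF=%.6g;MAF=%.6g;MAC=%d;LOG2OR=%.4f;TIER=%s",
                  calls$p_raw, calls$p_bonf, calls$tumor_maf,
                  as.integer(calls$tumor_mac), calls$log2_or, tier)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  filt, info)
  writeLines(c(header, body), path)
  invisible(path)
}
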