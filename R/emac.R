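#' Expected mutant allele count in RNA-seq
#'
#' E = RNA-seq depth at the site x DNA-seq mutant allele frequency: the
#' number of mutant RNA reads expected at a DNA-called SNV if the
#' variant is expressed proportionally. E predicts whether RNA-seq can
#' confirm the DNA call.
#'
#' @param rna_depth RNA-seq depth at the site (reads).
#' @param dna_maf DNA-seq mutant allele frequency in `[0, 1]`.
#' @return E, vectorized.
#' @export
emac <- function(rna_depth, dna_maf) {
  if (any(rna_depth < 0)) abort("rna_depth must be >= 0")
  if (any(dna_maf < 0 | dna_maf > 1)) abort("dna_maf must be in [0, 1]")
  rna_depth * dna_maf
}

#' Build EMAC validation records for DNA calls
#'
#' Pairs each DNA-called variant with its RNA-seq depth and mutant read
#' count, computes E, and flags coverage (at least one RNA read) and
#' confirmation (covered and at least `min_rna_mac` mutant RNA reads).
#'
#' @param calls DNA call tibble with `chrom`, `pos` and `tumor_maf`.
#' @param rna Tibble with `chrom`, `pos`, `rna_depth`, `rna_mac`.
#' @param min_rna_mac Mutant RNA reads required for confirmation.
#' @return Tibble of EMAC records with columns `E`, `covered`,
#'   `confirmed` appended.
#' @export
emac_records <- function(calls, rna, min_rna_mac = 1) {
  assert_columns(calls, c("chrom", "pos", "tumor_maf"), "calls")
  assert_columns(rna, c("chrom", "pos", "rna_depth", "rna_mac"), "rna")
  out <- dplyr::inner_join(as_tibble(calls), as_tibble(rna),
                           by = c("chrom", "pos"))
  mutate(out,
         E = emac(.data$rna_depth, .data$tumor_maf),
         covered = .data$rna_depth >= 1,
         confirmed = .data$covered & .data$rna_mac >= min_rna_mac)
}

#' Confirmation rates stratified by expected mutant allele count
#'
#' For each cutoff t, the fraction of records with E >= t that are
#' confirmed by RNA-seq, plus the low-expectation stratum
#' E < min(cutoffs). Empty strata are omitted.
#'
#' @param records EMAC records from [emac_records()] (columns `E`,
#'   `confirmed`).
#' @param cutoffs E thresholds, default `c(1, 2, 3)`.
#' @return Tibble with columns `stratum`, `cutoff`, `confirmed`,
#'   `total`, `rate`.
#' @export
confirmation_rates <- function(records, cutoffs = c(1, 2, 3)) {
  assert_columns(records, c("E", "confirmed"), "records")
  if (!nrow(records)) {
    return(tibble(stratum = character(), cutoff = numeric(),
                  confirmed = integer(), total = integer(), rate = numeric()))
  }
  cutoffs <- sort(cutoffs)
  strata <- lapply(cutoffs, function(t) {
    sel <- records$E >= t
    tibble(stratum = sprintf("E>=%g", t), cutoff = t,
           confirmed = sum(records$confirmed[sel]), total = sum(sel))
  })
  below <- records$E < cutoffs[1]
  strata <- c(strata, list(
    tibble(stratum = sprintf("E<%g", cutoffs[1]), cutoff = NA_real_,
           confirmed = sum(records$confirmed[below]), total = sum(below))
  ))
  bind_rows(strata) |>
    filter(.data$total > 0) |>
    mutate(rate = .data$confirmed / .data$total)
}
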