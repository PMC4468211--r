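#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join semi_join n row_number lag lead across
#' @importFrom stats dbinom pbinom rbinom pchisq p.adjust median rnbinom
#'   runif quantile dnorm sd setNames
#' @importFrom utils head tail
NULL

# Single run seed -> independent per-stage seeds, all < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    depth = 11L, pileup = 23L, rna = 37L, subsample = 41L,
    hmm = 53L, panel = 67L, generic = 79L
  )
  off <- offsets[[stage]] %||% offsets[["generic"]]
  as.integer((as.numeric(seed) * 2654435.0 + off) %% 2147483647)
}

# Chromosome dialect ("chr1" vs "1") must be consistent; coordinates are
# 1-based inclusive everywhere inside the package.
check_chrom_dialect <- function(chroms, reference_chroms = NULL, what = "input") {
  has_prefix <- grepl("^chr", chroms)
  if (length(chroms) && !all(has_prefix) && any(has_prefix)) {
    abort(sprintf("mixed chromosome name dialects within %s ('chr1' vs '1')", what))
  }
  if (!is.null(reference_chroms) && length(chroms) && length(reference_chroms)) {
    ref_prefix <- all(grepl("^chr", reference_chroms))
    if (all(has_prefix) != ref_prefix) {
      abort(sprintf(
        "chromosome dialect of %s does not match the target file dialect", what
      ))
    }
  }
  invisible(chroms)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
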