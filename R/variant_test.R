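#' Site-level SNV significance test, tumor vs pooled normal
#'
#' One-sided binomial likelihood-ratio test of a common mutant-allele
#' rate in tumor and pooled normal against the alternative that the
#' tumor rate is higher. The deviance is referred to a 1-df chi-square
#' distribution and the p-value halved for one-sidedness; sites where
#' the tumor rate does not exceed the pooled-normal rate get p = 1.
#'
#' The log2 odds ratio contrasts tumor mutant odds with pooled-normal
#' mutant odds; a continuity constant of 0.5 is added to all four cells
#' only when any cell is zero, so the statistic is always finite.
#'
#' Sites with zero depth in either sample are skipped (`p_raw` and
#' `log2_or` set to `NA`, `skipped_reason` recorded) because the
#' contrast is undefined there.
#'
#' @param counts Site-count tibble with columns `tumor_depth`,
#'   `tumor_mac`, `normal_depth`, `normal_mac` (see
#'   [read_counts_table()]).
#' @return `counts` with columns `tumor_maf`, `p_raw`, `log2_or` and
#'   `skipped_reason` added.
#' @examples
#' test_sites(tibble::tibble(tumor_depth = 1000, tumor_mac = 50,
#'                           normal_depth = 10000, normal_mac = 1))
#' @export
test_sites <- function(counts) {
  assert_columns(counts, c("tumor_depth", "tumor_mac",
                           "normal_depth", "normal_mac"), "counts")
  counts <- validate_site_counts(counts)
  dt <- counts$tumor_depth; mt <- counts$tumor_mac
  dn <- counts$normal_depth; mn <- counts$normal_mac

  ok <- dt > 0 & dn > 0
  p_raw <- rep(NA_real_, nrow(counts))
  rate_t <- ifelse(dt > 0, mt / dt, 0)
  rate_n <- ifelse(dn > 0, mn / dn, 0)
  p0 <- ifelse(dt + dn > 0, (mt + mn) / (dt + dn), 0)
  ll0 <- dbinom(mt, dt, p0, log = TRUE) + dbinom(mn, dn, p0, log = TRUE)
  ll1 <- dbinom(mt, dt, rate_t, log = TRUE) + dbinom(mn, dn, rate_n, log = TRUE)
  dev <- pmax(0, 2 * (ll1 - ll0))
  p <- 0.5 * pchisq(dev, df = 1, lower.tail = FALSE)
  p_raw[ok] <- ifelse(rate_t[ok] > rate_n[ok], p[ok], 1)

  zero_cell <- mt == 0 | (dt - mt) == 0 | mn == 0 | (dn - mn) == 0
  c0 <- ifelse(zero_cell, 0.5, 0)
  log2_or <- ifelse(ok,
                    log2((mt + c0) / (dt - mt + c0)) -
                      log2((mn + c0) / (dn - mn + c0)),
                    NA_real_)
  mutate(counts,
         p_raw = p_raw,
         log2_or = log2_or,
         skipped_reason = ifelse(ok, NA_character_, "zero depth in tumor or pooled normal"))
}

#' @rdname test_sites
#' @param tumor_depth,tumor_mac,normal_depth,normal_mac Scalar counts
#'   for a single site.
#' @export
site_test <- function(tumor_depth, tumor_mac, normal_depth, normal_mac) {
  if (tumor_depth <= 0 || normal_depth <= 0) {
    abort("site skipped: zero depth in tumor or pooled normal")
  }
  res <- test_sites(tibble(tumor_depth = tumor_depth, tumor_mac = tumor_mac,
                           normal_depth = normal_depth, normal_mac = normal_mac))
  list(p_raw = res$p_raw, log2_or = res$log2_or)
}

#' Apply the four-filter significant-SNV call chain
#'
#' A tested site is a significant SNV call when all four filters pass
#' (thresholds inclusive): Bonferroni-adjusted p-value `<= alpha`
#' (adjustment over the number of sites tested in the run), tumor MAF
#' `>= min_maf`, tumor MAC `>= min_mac`, and log2 odds ratio
#' `>= min_log2or` (i.e. tumor mutant odds at least `2^min_log2or` times
#' the pooled-normal odds). Defaults are alpha 0.001, MAF 0.005, MAC 5
#' and log2 OR 4.
#'
#' @param calls Output of [test_sites()].
#' @param n_tested Bonferroni denominator; defaults to the number of
#'   non-skipped sites in `calls`.
#' @param alpha,min_maf,min_mac,min_log2or Filter thresholds.
#' @return `calls` with `p_bonf`, per-filter `pass_*` flags, and the
#'   conjunction `pass`.
#' @export
filter_calls <- function(calls, n_tested = NULL, alpha = 0.001,
                         min_maf = 0.005, min_mac = 5, min_log2or = 4) {
  assert_columns(calls, c("p_raw", "log2_or", "tumor_maf", "tumor_mac"),
                 "calls")
  if (is.null(n_tested)) n_tested <- sum(!is.na(calls$p_raw))
  if (n_tested < 1) abort("n_tested must be >= 1")
  out <- mutate(as_tibble(calls),
                p_bonf = pmin(1, .data$p_raw * n_tested),
                pass_pbonf = !is.na(.data$p_bonf) & .data$p_bonf <= alpha,
                pass_maf = .data$tumor_maf >= min_maf,
                pass_mac = .data$tumor_mac >= min_mac,
                pass_log2or = !is.na(.data$log2_or) & .data$log2_or >= min_log2or,
                pass = .data$pass_pbonf & .data$pass_maf &
                  .data$pass_mac & .data$pass_log2or)
  attr(out, "filters") <- list(n_tested = n_tested, alpha = alpha,
                               min_maf = min_maf, min_mac = min_mac,
                               min_log2or = min_log2or)
  out
}

#' Refine calls against a curated position list
#'
#' Keeps only calls whose (chrom, pos) appears in the curated list and
#' records the list tier on the surviving calls. Used to restrict
#' tumor-only calls to positions with prior evidence (a conservative
#' expert-curated hotspot list, or a broader database-derived one).
#'
#' @param calls Call tibble with `chrom` and `pos`.
#' @param positions Curated list from [read_position_list()].
#' @return The subset of `calls` at listed positions, with a `tier`
#'   column.
#' @export
refine_by_list <- function(calls, positions) {
  assert_columns(calls, c("chrom", "pos"), "calls")
  assert_columns(positions, c("chrom", "pos", "tier"), "positions")
  if (nrow(calls) && nrow(positions)) {
    check_chrom_dialect(unique(calls$chrom), unique(positions$chrom), "calls")
  }
  key <- dplyr::distinct(select(as_tibble(positions),
                                "chrom", "pos", "tier"))
  out <- dplyr::inner_join(as_tibble(calls), key, by = c("chrom", "pos"))
  if ("tier.y" %in% names(out)) {  # calls already carried a tier column
    out$tier <- out$tier.y
    out$tier.x <- out$tier.y <- NULL
  }
  out
}

#' Leave-one-out pooled normal
#'
#' For a cohort with matched normals, the pooled control for sample i
#' aggregates the per-site depths and mutant counts of every other
#' sample's normal (pool size n - 1).
#'
#' @param normals List of per-sample count tibbles, each with `chrom`,
#'   `pos`, `depth`, `mac`.
#' @param held_out Index of the sample excluded from the pool.
#' @return Tibble with per-site `normal_depth` and `normal_mac` summed
#'   over the pool members.
#' @export
build_loo_pool <- function(normals, held_out) {
  if (length(normals) < 2) abort("leave-one-out pool needs >= 2 normal samples")
  if (held_out < 1 || held_out > length(normals)) {
    abort("held_out index out of range")
  }
  members <- normals[-held_out]
  bind_rows(members) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(normal_depth = sum(.data$depth),
              normal_mac = sum(.data$mac), .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
}

#' Subsample a pooled-normal count table
#'
#' Binomial thinning of per-site depth and mutant counts at a fixed
#' fraction (used to shrink a deep pooled normal to a library size
#' comparable with a single tumor). Mutant reads are thinned first and
#' reference reads independently, so `mac <= depth` is preserved and the
#' expected depth is `fraction x` the original.
#'
#' @param pool Tibble with `normal_depth` and `normal_mac`.
#' @param fraction Retention fraction in (0, 1].
#' @param seed Integer seed; identical seeds give identical output.
#' @return `pool` with thinned counts.
#' @export
subsample_pool <- function(pool, fraction, seed = 1L) {
  assert_columns(pool, c("normal_depth", "normal_mac"), "pool")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (fraction == 1) return(as_tibble(pool))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "subsample"))
  mac <- rbinom(nrow(pool), pool$normal_mac, fraction)
  refs <- rbinom(nrow(pool), pool$normal_depth - pool$normal_mac, fraction)
  mutate(as_tibble(pool), normal_mac = mac, normal_depth = mac + refs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
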