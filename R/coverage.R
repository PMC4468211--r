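#' Remove reads with low mapping quality
#'
#' Reads with Phred-scaled mapping quality below `min_mapq` are dropped
#' (default MapQ < 5, i.e. less than ~70% mapping accuracy); order of the
#' surviving reads is preserved and the operation is idempotent.
#'
#' @param reads Tibble with at least a `mapq` column (one row per
#'   aligned read).
#' @param min_mapq Minimum mapping quality kept (inclusive).
#' @return The subset of `reads` with `mapq >= min_mapq`.
#' @export
filter_by_mapq <- function(reads, min_mapq = 5) {
  assert_columns(reads, "mapq", "reads")
  filter(as_tibble(reads), .data$mapq >= min_mapq)
}

#' Trim read ends by base-call quality
#'
#' From each end of a read, terminal windows of `run_len` consecutive
#' bases are removed repeatedly while the window's mean Phred base-call
#' quality (CallQ) is at or below `q_thresh` (default CallQ <= 20, i.e.
#' <= 99% per-base accuracy). A read trimmed below `run_len` bases is
#' dropped entirely.
#'
#' @param base_quals Integer vector of per-base call qualities for one
#'   read, or a list of such vectors.
#' @param q_thresh Quality threshold; a terminal window with mean CallQ
#'   at or below this is removed.
#' @param run_len Number of consecutive terminal bases averaged per
#'   trimming step.
#' @return The retained quality vector (possibly empty), or a list of
#'   them when `base_quals` is a list.
#' @export
trim_by_callq <- function(base_quals, q_thresh = 20, run_len = 5) {
  if (run_len < 1) abort("run_len must be >= 1")
  if (is.list(base_quals)) {
    return(purrr::map(base_quals, trim_by_callq,
                      q_thresh = q_thresh, run_len = run_len))
  }
  q <- base_quals
  if (length(q) < run_len) return(q)  # no terminal window to evaluate
  repeat {
    if (length(q) < run_len) return(q[0])  # trimmed below run_len: drop
    trimmed <- FALSE
    if (mean(q[seq_len(run_len)]) <= q_thresh) {
      q <- q[-seq_len(run_len)]
      trimmed <- TRUE
    }
    if (length(q) >= run_len &&
        mean(q[seq.int(length(q) - run_len + 1L, length(q))]) <= q_thresh) {
      q <- q[seq_len(length(q) - run_len)]
      trimmed <- TRUE
    }
    if (!trimmed) return(q)
  }
}

#' Breadth of coverage at depth thresholds
#'
#' Fraction of targeted bases covered at or above each depth threshold
#' (e.g. 1x, 20x, 50x, 100x). Monotone non-increasing in the threshold.
#'
#' @param depth Numeric vector of per-base depths over the targeted
#'   bases.
#' @param thresholds Positive integer depth cutoffs.
#' @return Tibble with columns `threshold` and `breadth`.
#' @export
breadth_of_coverage <- function(depth, thresholds = c(1, 20, 50, 100)) {
  if (!length(depth)) abort("no targeted bases: depth track is empty")
  if (any(thresholds <= 0)) abort("thresholds must be positive")
  tibble(
    threshold = as.numeric(thresholds),
    breadth = vapply(thresholds, function(t) mean(depth >= t), numeric(1))
  )
}

#' Reads per region kilobase per million mapped reads
#'
#' RPKM = reads in region / (region length in kb x total mapped reads in
#' millions); the panel's per-region coverage normalization.
#'
#' @param region_length Region length in bases (`end - start + 1`).
#' @param reads_in_region Read count overlapping the region.
#' @param total_mapped_reads Library total of mapped (targeted) reads.
#' @return RPKM value(s); vectorized over regions.
#' @export
rpkm <- function(region_length, reads_in_region, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) abort("total_mapped_reads must be > 0")
  if (any(region_length <= 0)) abort("region length must be > 0")
  reads_in_region / ((region_length / 1e3) * (total_mapped_reads / 1e6))
}

#' Order-statistic confidence interval for a median
#'
#' Approximate level-`level` CI for the median from the order statistics
#' at ranks `ceiling(n/2 - z*sqrt(n)/2)` and
#' `ceiling(n/2 + 1 + z*sqrt(n)/2)`, clipped to `[1, n]`, with `z` the
#' standard normal quantile for the chosen level.
#'
#' @param values Numeric sample (n >= 1).
#' @param level Confidence level, default 0.95.
#' @return Tibble with one row: `median`, `lower`, `upper`, `n`.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) abort("median_ci needs at least one value")
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- sort(values)
  lo <- min(n, max(1L, as.integer(ceiling(n / 2 - z * sqrt(n) / 2))))
  hi <- min(n, max(1L, as.integer(ceiling(n / 2 + 1 + z * sqrt(n) / 2))))
  tibble(median = median(values), lower = s[lo], upper = s[hi], n = n)
}

#' Panel coverage QC report
#'
#' Combines the per-base depth track with the panel definition into the
#' standard capture QC metrics: breadth of coverage at the usual depth
#' thresholds, base-level on-target rate (aligned bases falling in
#' targets over all aligned bases), per-region RPKM and the median RPKM
#' with its order-statistic CI. Read counts per region are recovered
#' from the depth track as `sum(depth) / read_length`.
#'
#' @param depth Tibble depth track with columns `chrom`, `pos`, `depth`
#'   covering the analyzed span (on- and off-target bases).
#' @param targets Target regions as returned by [read_bed()].
#' @param thresholds Depth cutoffs for breadth of coverage.
#' @param read_length Read length used to convert summed base depth to
#'   read counts for RPKM.
#' @return A list of class `coverage_report` with elements `breadth`,
#'   `on_target_rate`, `rpkm_per_region`, `median_rpkm` and `summary`.
#' @export
coverage_report <- function(depth, targets, thresholds = c(1, 20, 50, 100),
                            read_length = 100) {
  assert_columns(depth, c("chrom", "pos", "depth"), "depth track")
  assert_columns(targets, c("chrom", "start", "end"), "targets")
  check_chrom_dialect(unique(depth$chrom), unique(targets$chrom), "depth track")

  on_target <- rep(FALSE, nrow(depth))
  region_reads <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    sel <- depth$chrom == targets$chrom[i] &
      depth$pos >= targets$start[i] & depth$pos <= targets$end[i]
    on_target[sel] <- TRUE
    region_reads[i] <- sum(depth$depth[sel]) / read_length
  }
  total_aligned <- sum(depth$depth)
  on_rate <- if (total_aligned > 0) sum(depth$depth[on_target]) / total_aligned else NA_real_
  total_reads <- total_aligned / read_length
  reg <- mutate(as_tibble(targets),
                length = .data$end - .data$start + 1,
                reads = region_reads,
                rpkm = rpkm(.data$length, region_reads, total_reads))
  res <- list(
    breadth = breadth_of_coverage(depth$depth[on_target], thresholds),
    on_target_rate = on_rate,
    rpkm_per_region = reg,
    median_rpkm = median_ci(reg$rpkm),
    summary = tibble(
      targeted_bases = sum(on_target),
      total_aligned_bases = total_aligned,
      mean_target_depth = mean(depth$depth[on_target])
    )
  )
  structure(res, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Panel coverage report\n")
  cat(sprintf("  targeted bases: %d, mean target depth: %.1fx\n",
              x$summary$targeted_bases, x$summary$mean_target_depth))
  cat(sprintf("  on-target rate (bases): %.1f%%\n", 100 * x$on_target_rate))
  for (i in seq_len(nrow(x$breadth))) {
    cat(sprintf("  breadth >= %dx: %.1f%%\n", x$breadth$threshold[i],
                100 * x$breadth$breadth[i]))
  }
  cat(sprintf("  median RPKM: %.1f (approx. 95%% CI %.1f-%.1f)\n",
              x$median_rpkm$median, x$median_rpkm$lower, x$median_rpkm$upper))
  invisible(x)
}
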