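#' Restriction-imposed flexible windows from a pooled-normal depth track
#'
#' Tiles each chromosome with variable-width windows scanned left to
#' right. A window closes at the first base where both restrictions
#' hold: (a) the mean per-base pooled-normal depth over the window is at
#' least `min_depth_per_sample x n_pool_samples` and (b) the window is
#' at least `min_width` bases wide. A terminal remainder that fails
#' either restriction is merged into the previous window, so windows
#' tile the chromosome exactly and every non-terminal window satisfies
#' both criteria. Both on-target and off-target coverage contribute.
#'
#' A chromosome with zero coverage yields a single window flagged
#' `low_coverage`, which downstream steps exclude from segmentation.
#'
#' @param normal_depth Pooled-normal per-base depth tibble with columns
#'   `chrom`, `pos`, `depth`; positions contiguous within a chromosome.
#' @param n_pool_samples Number of samples aggregated in the pool.
#' @param min_depth_per_sample Minimum mean per-base depth per pool
#'   member (default 20x).
#' @param min_width Minimum window width in bases (default 20 kbp).
#' @return Tibble of windows: `chrom`, `start`, `end`, `width`,
#'   `normal_depth_sum`, `mean_depth`, `low_coverage`.
#' @export
build_windows <- function(normal_depth, n_pool_samples,
                          min_depth_per_sample = 20, min_width = 20000) {
  assert_columns(normal_depth, c("chrom", "pos", "depth"), "depth track")
  if (n_pool_samples < 1 || min_depth_per_sample <= 0 || min_width < 1) {
    abort("windowing parameters must be positive")
  }
  thr <- min_depth_per_sample * n_pool_samples
  normal_depth |>
    as_tibble() |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ windows_one_chrom(.x, thr, min_width)) |>
    ungroup()
}

# Left-to-right scan on one chromosome. With cs the cumulative depth and
# g[e] = cs[e] - thr * e, the restriction sum(depth[s..e]) >= thr * width
# is g[e] >= g[s - 1], so each window end is the first index past the
# min-width point where g re-attains its value at the window start.
windows_one_chrom <- function(track, thr, min_width) {
  o <- order(track$pos)
  pos <- track$pos[o]
  depth <- track$depth[o]
  L <- length(pos)
  if (sum(depth) == 0) {
    return(tibble(start = pos[1], end = pos[L], width = pos[L] - pos[1] + 1,
                  normal_depth_sum = 0, mean_depth = 0, low_coverage = TRUE))
  }
  cs <- cumsum(depth)
  g <- cs - thr * seq_len(L)
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  while (s <= L) {
    e_min <- s + min_width - 1L
    if (e_min > L) { e_hit <- NA_integer_ } else {
      target <- if (s == 1L) 0 else g[s - 1L]
      rel <- which(g[e_min:L] >= target - 1e-9)
      e_hit <- if (length(rel)) e_min + rel[1L] - 1L else NA_integer_
    }
    if (is.na(e_hit)) {
      # terminal remainder: merge into the previous window
      if (length(ends)) {
        ends[length(ends)] <- L
      } else {
        starts <- s; ends <- L
      }
      break
    }
    starts <- c(starts, s); ends <- c(ends, e_hit)
    s <- e_hit + 1L
  }
  sums <- cs[ends] - c(0, cs[starts[-1L] - 1L])
  width <- ends - starts + 1L
  tibble(
    start = pos[starts], end = pos[ends], width = width,
    normal_depth_sum = sums, mean_depth = sums / width,
    low_coverage = FALSE
  )
}

#' Count per-window read depth from a per-base track
#'
#' Sums a per-base depth track over a set of windows (or any interval
#' table); used to attach tumor and pooled-normal counts to the flexible
#' windows before computing copy-number ratios.
#'
#' @param windows Interval tibble with `chrom`, `start`, `end`.
#' @param depth Per-base depth tibble (`chrom`, `pos`, `depth`).
#' @param name Output column name.
#' @return `windows` with the summed-depth column appended.
#' @export
count_in_windows <- function(windows, depth, name = "count") {
  assert_columns(windows, c("chrom", "start", "end"), "windows")
  assert_columns(depth, c("chrom", "pos", "depth"), "depth track")
  out <- as_tibble(windows)
  vals <- numeric(nrow(out))
  for (ch in unique(out$chrom)) {
    sel <- depth$chrom == ch
    pos <- depth$pos[sel]; d <- depth$depth[sel]
    o <- order(pos); pos <- pos[o]; d <- d[o]
    cs <- c(0, cumsum(d))
    wi <- which(out$chrom == ch)
    lo <- findInterval(out$start[wi] - 1L, pos)
    hi <- findInterval(out$end[wi], pos)
    vals[wi] <- cs[hi + 1L] - cs[lo + 1L]
  }
  out[[name]] <- vals
  out
}
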