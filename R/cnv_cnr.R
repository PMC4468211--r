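#' Per-window log2 copy-number ratios
#'
#' Library-size normalized log2 ratio of tumor to pooled-normal reads
#' per window: `cnr_w = log2((t_w / T) / (n_w / N))` with T and N the
#' library sizes. Windows with zero pooled-normal count are masked
#' (`cnr = NA`); the ratio is invariant under joint rescaling of a
#' library's counts and size.
#'
#' @param windows Window tibble from [build_windows()] (or any interval
#'   tibble with `chrom`, `start`, `end`).
#' @param tumor_counts,normal_counts Per-window read counts.
#' @param tumor_lib,normal_lib Library sizes; default to the count
#'   totals.
#' @return A `cnr_profile` tibble: `windows` columns plus
#'   `tumor_count`, `normal_count`, `cnr`, `masked`; attributes record
#'   the library sizes and centering state.
#' @export
compute_cnr <- function(windows, tumor_counts, normal_counts,
                        tumor_lib = sum(tumor_counts),
                        normal_lib = sum(normal_counts)) {
  assert_columns(windows, c("chrom", "start", "end"), "windows")
  if (length(tumor_counts) != nrow(windows) ||
      length(normal_counts) != nrow(windows)) {
    abort("per-window counts must match the number of windows")
  }
  if (tumor_lib <= 0 || normal_lib <= 0) abort("library sizes must be > 0")
  low <- if ("low_coverage" %in% names(windows)) windows$low_coverage else
    rep(FALSE, nrow(windows))
  masked <- normal_counts <= 0 | low
  if (all(masked)) abort("all windows masked: no usable pooled-normal coverage")
  cnr <- ifelse(masked, NA_real_,
                log2((tumor_counts / tumor_lib) / (normal_counts / normal_lib)))
  out <- mutate(as_tibble(windows),
                tumor_count = tumor_counts, normal_count = normal_counts,
                cnr = cnr, masked = masked)
  attr(out, "tumor_lib") <- tumor_lib
  attr(out, "normal_lib") <- normal_lib
  attr(out, "centered") <- FALSE
  class(out) <- c("cnr_profile", class(out))
  out
}

#' Center a copy-number-ratio profile at its genome-wide median
#'
#' Subtracts the genome-wide median CNR (over unmasked windows) from
#' every window so that copy-number-neutral regions sit at zero.
#' Idempotent: centering a centered profile changes nothing.
#'
#' @param profile A `cnr_profile` from [compute_cnr()].
#' @return The centered profile (`attr(., "centered")` is `TRUE`,
#'   `attr(., "center_shift")` records the subtracted median).
#' @export
center_cnr <- function(profile) {
  assert_columns(profile, c("cnr", "masked"), "profile")
  usable <- profile$cnr[!profile$masked]
  if (!length(usable)) abort("cannot center: no unmasked windows")
  shift <- median(usable)
  prev <- attr(profile, "center_shift") %||% 0
  out <- mutate(profile, cnr = .data$cnr - shift)
  attr(out, "centered") <- TRUE
  attr(out, "center_shift") <- prev + shift
  for (a in c("tumor_lib", "normal_lib")) attr(out, a) <- attr(profile, a)
  if (!inherits(out, "cnr_profile")) class(out) <- c("cnr_profile", class(out))
  out
}

#' Per-base gene-level copy number
#'
#' Exon-resolution copy-number track for a gene: at every base of the
#' gene's target regions, the library-normalized log2 ratio of tumor to
#' pooled-normal per-base depth. Bases with zero pooled-normal depth are
#' masked and omitted.
#'
#' @param gene_regions Target regions of the gene ([read_bed()] rows).
#' @param tumor_depth,normal_depth Per-base depth tibbles (`chrom`,
#'   `pos`, `depth`).
#' @param tumor_lib,normal_lib Library sizes; default to the track
#'   totals.
#' @return Tibble with `gene_id`, `chrom`, `pos`, `tumor_depth`,
#'   `normal_depth`, `log2_ratio` for every unmasked base.
#' @export
gene_level_cnv <- function(gene_regions, tumor_depth, normal_depth,
                           tumor_lib = sum(tumor_depth$depth),
                           normal_lib = sum(normal_depth$depth)) {
  assert_columns(gene_regions, c("chrom", "start", "end"), "gene regions")
  if (!nrow(gene_regions)) abort("gene_regions must be non-empty")
  if (tumor_lib <= 0 || normal_lib <= 0) abort("library sizes must be > 0")
  gene <- if ("gene_id" %in% names(gene_regions)) gene_regions$gene_id else
    rep(NA_character_, nrow(gene_regions))
  pieces <- lapply(seq_len(nrow(gene_regions)), function(i) {
    sel_t <- tumor_depth$chrom == gene_regions$chrom[i] &
      tumor_depth$pos >= gene_regions$start[i] &
      tumor_depth$pos <= gene_regions$end[i]
    sel_n <- normal_depth$chrom == gene_regions$chrom[i] &
      normal_depth$pos >= gene_regions$start[i] &
      normal_depth$pos <= gene_regions$end[i]
    t_sub <- tumor_depth[sel_t, c("pos", "depth")]
    n_sub <- normal_depth[sel_n, c("pos", "depth")]
    names(t_sub)[2] <- "tumor_depth"; names(n_sub)[2] <- "normal_depth"
    x <- dplyr::inner_join(t_sub, n_sub, by = "pos")
    x$gene_id <- gene[i]; x$chrom <- gene_regions$chrom[i]
    x
  })
  bind_rows(pieces) |>
    filter(.data$normal_depth > 0) |>
    mutate(log2_ratio = log2((.data$tumor_depth / tumor_lib) /
                               (.data$normal_depth / normal_lib))) |>
    select("gene_id", "chrom", "pos", "tumor_depth", "normal_depth",
           "log2_ratio")
}
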