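#' @importFrom ggplot2 ggplot aes geom_point geom_segment geom_line
#'   geom_hline geom_vline labs theme_minimal scale_x_log10 scale_y_log10
#'   facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a copy-number-ratio profile with its segmentation
#'
#' Windows are drawn as points at their midpoints; fitted segments, when
#' supplied, overlay as horizontal lines at the segment mean CNR.
#'
#' @param object A `cnr_profile`.
#' @param segmentation Optional `cnv_segmentation` over the same
#'   profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnr_profile <- function(object, segmentation = NULL, ...) {
  df <- filter(as_tibble(object), !.data$masked) |>
    mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot(df, aes(x = .data$mid / 1e6, y = .data$cnr)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = expression(log[2] ~ "copy-number ratio")) +
    theme_minimal()
  if (!is.null(segmentation)) {
    segs <- tidy(segmentation)
    p <- p + geom_segment(
      data = segs,
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$mean_cnr, yend = .data$mean_cnr),
      colour = "red", linewidth = 1, inherit.aes = FALSE
    )
  }
  p
}

#' Plot breadth of coverage
#'
#' Fraction of targeted bases at or above each depth threshold, from a
#' [coverage_report()].
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_report <- function(object, ...) {
  ggplot(object$breadth, aes(x = .data$threshold, y = 100 * .data$breadth)) +
    geom_line() + geom_point() +
    labs(x = "depth threshold (x)", y = "targeted bases covered (%)") +
    theme_minimal()
}

#' Plot gene-burden significance from a significantly-mutated-gene fit
#'
#' Genes ordered by FDR-adjusted q-value; the FDR threshold is drawn as
#' a dashed line and significant genes are highlighted.
#'
#' @param object An `smg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.smg_fit <- function(object, ...) {
  df <- tidy(object) |> mutate(rank = row_number())
  ggplot(df, aes(x = .data$rank, y = -log10(pmax(.data$q_fdr, 1e-300)),
                 colour = .data$significant)) +
    geom_point() +
    geom_hline(yintercept = -log10(object$fdr), linetype = "dashed") +
    labs(x = "gene rank", y = expression(-log[10] ~ "q"),
         colour = sprintf("q <= %g", object$fdr)) +
    theme_minimal()
}

#' Plot RNA-seq validation of DNA calls on the EMAC plane
#'
#' RNA-seq depth against DNA-seq MAF on log axes, confirmed and
#' unconfirmed calls distinguished, with dashed iso-lines at expected
#' mutant allele counts E = 1, 2, 3.
#'
#' @param records EMAC records from [emac_records()].
#' @param e_lines E values for the dashed iso-lines.
#' @return A ggplot object.
#' @export
plot_emac <- function(records, e_lines = c(1, 2, 3)) {
  assert_columns(records, c("rna_depth", "tumor_maf", "confirmed"), "records")
  df <- filter(as_tibble(records), .data$rna_depth > 0, .data$tumor_maf > 0)
  iso <- purrr::map_dfr(e_lines, function(e) {
    maf <- 10^seq(log10(min(df$tumor_maf)), log10(max(df$tumor_maf)),
                  length.out = 50)
    tibble(E = e, tumor_maf = maf, rna_depth = e / maf)
  })
  ggplot(df, aes(x = .data$tumor_maf, y = .data$rna_depth)) +
    geom_line(data = iso, aes(group = .data$E), linetype = "dashed",
              colour = "grey50") +
    geom_point(aes(shape = .data$confirmed, colour = .data$confirmed)) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "DNA-seq MAF", y = "RNA-seq depth",
         shape = "confirmed", colour = "confirmed") +
    theme_minimal()
}
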