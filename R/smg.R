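#' Significantly-mutated-gene test
#'
#' Gene-length adjusted binomial test of mutation burden against the
#' cohort background rate. Every tested base in every sample is treated
#' as one Bernoulli trial, so gene g with `tested_bases` L_g and cohort
#' size S contributes L_g x S trials. The background rate is estimated
#' from the cohort itself as
#' `r_hat = sum(observed_snv) / sum(tested_bases * n_samples)`, each
#' gene's p-value is the upper binomial tail `P(X >= k_g)` with
#' `X ~ Binomial(L_g * S_g, r_hat)`, and false discovery rate control is
#' Benjamini-Hochberg with significance at `q <= fdr`.
#'
#' @param genes Tibble with columns `gene_id`, `tested_bases`,
#'   `n_samples`, `observed_snv`.
#' @param fdr FDR threshold for the `significant` flag.
#' @return An object of class `smg_fit`; use [tidy()][generics::tidy]
#'   for the per-gene table and [glance()][generics::glance] for the
#'   fit-level summary.
#' @examples
#' genes <- tibble::tibble(gene_id = c("A", "B"),
#'                         tested_bases = c(1000, 1000),
#'                         n_samples = 10, observed_snv = c(5, 0))
#' tidy(smg_test(genes))
#' @export
smg_test <- function(genes, fdr = 0.05) {
  assert_columns(genes, c("gene_id", "tested_bases", "n_samples",
                          "observed_snv"), "genes")
  if (any(genes$tested_bases <= 0)) abort("tested_bases must be > 0")
  if (any(genes$observed_snv < 0)) abort("observed_snv must be >= 0")
  trials <- genes$tested_bases * genes$n_samples
  if (any(genes$observed_snv > trials)) {
    abort("observed_snv exceeds tested_bases x n_samples for some gene")
  }
  r_hat <- sum(genes$observed_snv) / sum(trials)
  # upper tail P(X >= k); k = 0 gives p = 1 by construction
  p <- pbinom(genes$observed_snv - 1, size = trials, prob = r_hat,
              lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tbl <- mutate(as_tibble(genes),
                background_rate = r_hat,
                p_binom = p,
                q_fdr = q,
                significant = q <= fdr)
  structure(list(genes = tbl, background_rate = r_hat, fdr = fdr),
            class = "smg_fit")
}

#' @export
print.smg_fit <- function(x, ...) {
  cat(sprintf("Significantly-mutated-gene fit: %d genes, background rate %.3g\n",
              nrow(x$genes), x$background_rate))
  cat(sprintf("  %d significant at FDR <= %g\n",
              sum(x$genes$significant), x$fdr))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.smg_fit <- function(x, ...) {
  arrange(x$genes, .data$q_fdr, .data$p_binom)
}

#' @exportS3Method generics::glance
glance.smg_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_significant = sum(x$genes$significant),
    background_rate = x$background_rate,
    total_snv = sum(x$genes$observed_snv),
    total_trials = sum(x$genes$tested_bases * x$genes$n_samples),
    fdr = x$fdr
  )
}
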