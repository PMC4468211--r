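#' Simulation configuration for synthetic panel data
#'
#' Bundles every parameter of the synthetic targeted-panel experiment:
#' genome layout, capture panel, depth model, sequencing error, planted
#' copy-number events and SNVs, pooled-normal composition and RNA-seq
#' depth. Defaults emulate the assay's study conditions: a pooled
#' normal of 8 samples, ~70% of aligned bases on target, deep on-target
#' coverage (mean 300x, negative-binomial with dispersion 0.1), and a
#' per-base sequencing error drawn uniformly from 0.001-0.002.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chroms,chrom_length Genome layout (contiguous chromosomes).
#' @param panel Target regions tibble (`chrom`, `start`, `end`,
#'   `gene_id`); `NULL` generates `n_targets` regions of width
#'   `target_width` per chromosome.
#' @param n_targets,target_width Auto-generated panel shape.
#' @param on_target_rate_true Fraction of aligned bases on target.
#' @param mean_depth Mean on-target per-base depth per sample.
#' @param dispersion Negative-binomial dispersion of depth (variance
#'   `mu + dispersion * mu^2`).
#' @param error_rate Length-2 range of the per-site sequencing error.
#' @param planted_cnv Tibble (`chrom`, `start`, `end`, `log2_ratio`) of
#'   copy-number events planted in the tumor.
#' @param planted_snv Tibble (`chrom`, `pos`, `maf`) of true somatic
#'   SNVs planted in the tumor.
#' @param n_pool_samples Number of normals aggregated in the pool.
#' @param n_null_sites Null (error-only) pileup sites simulated.
#' @param rna_mean_depth Mean RNA-seq depth at validated sites.
#' @param read_length Nominal read length (bases), used when converting
#'   depth to read counts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2, chrom_length = 200000L,
                       panel = NULL, n_targets = 20, target_width = 500L,
                       on_target_rate_true = 0.7, mean_depth = 300,
                       dispersion = 0.1, error_rate = c(0.001, 0.002),
                       planted_cnv = NULL, planted_snv = NULL,
                       n_pool_samples = 8, n_null_sites = 1000,
                       rna_mean_depth = 20, read_length = 100) {
  stopifnot(length(error_rate) == 2, all(error_rate >= 0),
            error_rate[1] <= error_rate[2],
            on_target_rate_true > 0, on_target_rate_true < 1,
            mean_depth > 0, n_pool_samples >= 1)
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = as.integer(chrom_length), panel = panel,
              n_targets = n_targets, target_width = as.integer(target_width),
              on_target_rate_true = on_target_rate_true,
              mean_depth = mean_depth, dispersion = dispersion,
              error_rate = error_rate, planted_cnv = planted_cnv,
              planted_snv = planted_snv, n_pool_samples = n_pool_samples,
              n_null_sites = n_null_sites, rna_mean_depth = rna_mean_depth,
              read_length = read_length)
  if (is.null(cfg$panel)) cfg$panel <- default_panel(cfg)
  bad <- cfg$panel$end > cfg$chrom_length | cfg$panel$start < 1
  if (any(bad)) abort("panel regions outside chromosome bounds")
  for (tb in list(cfg$planted_cnv, cfg$planted_snv)) {
    if (!is.null(tb) && nrow(tb) &&
        !all(tb$chrom %in% paste0("chr", seq_len(cfg$n_chroms)))) {
      abort("planted features must lie on simulated chromosomes")
    }
  }
  structure(cfg, class = "sim_config")
}

default_panel <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "panel"))
  purrr::map_dfr(seq_len(cfg$n_chroms), function(i) {
    starts <- sort(sample.int(cfg$chrom_length - cfg$target_width,
                              cfg$n_targets))
    tibble(chrom = paste0("chr", i), start = starts,
           end = starts + cfg$target_width - 1L,
           gene_id = sprintf("GENE%d_%02d", i, seq_along(starts)),
           panel_version = "sim1")
  })
}

#' Simulate tumor and pooled-normal depth tracks
#'
#' Per-base depths are negative-binomial around the configured mean,
#' with on-target bases at `mean_depth` and off-target bases scaled so
#' the base-level on-target rate matches `on_target_rate_true`. The
#' pooled-normal track sums `n_pool_samples` independent draws. Planted
#' copy-number events multiply the tumor mean by `2^log2_ratio` over
#' their span. Bit-reproducible under a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return List with `tumor` and `normal` depth tibbles (`chrom`, `pos`,
#'   `depth`) and a `truth` list carrying the planted events and
#'   on-target mask.
#' @export
simulate_depth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "depth"))

  chroms <- paste0("chr", seq_len(config$n_chroms))
  pos_tbl <- purrr::map_dfr(chroms, function(ch) {
    tibble(chrom = ch, pos = seq_len(config$chrom_length))
  })
  on_target <- rep(FALSE, nrow(pos_tbl))
  for (i in seq_len(nrow(config$panel))) {
    on_target[pos_tbl$chrom == config$panel$chrom[i] &
                pos_tbl$pos >= config$panel$start[i] &
                pos_tbl$pos <= config$panel$end[i]] <- TRUE
  }
  n_on <- sum(on_target); n_off <- sum(!on_target)
  r <- config$on_target_rate_true
  mu_off <- if (n_off > 0) config$mean_depth * n_on * (1 - r) / (r * n_off) else 0
  mu_base <- ifelse(on_target, config$mean_depth, mu_off)

  tumor_mu <- mu_base
  if (!is.null(config$planted_cnv) && nrow(config$planted_cnv)) {
    for (i in seq_len(nrow(config$planted_cnv))) {
      sel <- pos_tbl$chrom == config$planted_cnv$chrom[i] &
        pos_tbl$pos >= config$planted_cnv$start[i] &
        pos_tbl$pos <= config$planted_cnv$end[i]
      tumor_mu[sel] <- tumor_mu[sel] * 2^config$planted_cnv$log2_ratio[i]
    }
  }
  tumor <- mutate(pos_tbl, depth = vec_nb(tumor_mu, config$dispersion))
  normal_depth <- integer(nrow(pos_tbl))
  for (s in seq_len(config$n_pool_samples)) {
    normal_depth <- normal_depth + vec_nb(mu_base, config$dispersion)
  }
  normal <- mutate(pos_tbl, depth = normal_depth)
  list(tumor = tumor, normal = normal,
       truth = list(planted_cnv = config$planted_cnv,
                    on_target = on_target,
                    mean_depth = config$mean_depth, mu_off = mu_off))
}

vec_nb <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

#' Simulate tumor and pooled-normal pileup counts
#'
#' Generates per-site count records at the planted SNV positions plus
#' `n_null_sites` error-only panel positions. Tumor mutant counts are
#' binomial at the planted MAF (true sites) or at a per-site sequencing
#' error drawn from the configured range (null sites); the pooled
#' normal aggregates `n_pool_samples` independent error-only samples.
#'
#' @param config A [sim_config()].
#' @return Site-count tibble in the [read_counts_table()] schema plus
#'   truth columns `is_snv`, `true_maf`, `error_rate`.
#' @export
simulate_pileups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "pileup"))

  snv <- config$planted_snv
  panel_pos <- purrr::map_dfr(seq_len(nrow(config$panel)), function(i) {
    tibble(chrom = config$panel$chrom[i],
           pos = seq(config$panel$start[i], config$panel$end[i]))
  })
  if (!is.null(snv) && nrow(snv)) {
    panel_pos <- dplyr::anti_join(panel_pos, snv, by = c("chrom", "pos"))
  }
  n_null <- min(config$n_null_sites, nrow(panel_pos))
  null_sites <- panel_pos[sample.int(nrow(panel_pos), n_null), ]
  sites <- bind_rows(
    if (!is.null(snv) && nrow(snv)) {
      tibble(chrom = snv$chrom, pos = snv$pos, is_snv = TRUE,
             true_maf = snv$maf)
    },
    mutate(null_sites, is_snv = FALSE, true_maf = 0)
  ) |> arrange(.data$chrom, .data$pos)

  n <- nrow(sites)
  err <- runif(n, config$error_rate[1], config$error_rate[2])
  tumor_depth <- vec_nb(rep(config$mean_depth, n), config$dispersion)
  tumor_rate <- ifelse(sites$is_snv, sites$true_maf, err)
  tumor_mac <- rbinom(n, tumor_depth, tumor_rate)
  normal_depth <- integer(n); normal_mac <- integer(n)
  for (s in seq_len(config$n_pool_samples)) {
    d <- vec_nb(rep(config$mean_depth, n), config$dispersion)
    normal_depth <- normal_depth + d
    normal_mac <- normal_mac + rbinom(n, d, err)
  }
  mutate(sites,
         ref = "A", alt = "T",
         tumor_depth = tumor_depth, tumor_mac = tumor_mac,
         normal_depth = normal_depth, normal_mac = normal_mac,
         error_rate = err,
         tumor_maf = ifelse(tumor_depth > 0, tumor_mac / tumor_depth, 0)) |>
    select("chrom", "pos", "ref", "alt", "tumor_depth", "tumor_mac",
           "normal_depth", "normal_mac", "tumor_maf", "is_snv",
           "true_maf", "error_rate")
}

#' Simulate RNA-seq counts at DNA-called variant sites
#'
#' For each DNA call, draws an RNA-seq depth from a negative binomial
#' around `rna_mean_depth` and a mutant RNA read count binomial at the
#' DNA MAF, producing records ready for [emac_records()] /
#' [confirmation_rates()].
#'
#' @param dna_calls Call tibble with `chrom`, `pos`, `tumor_maf`.
#' @param config A [sim_config()].
#' @return Tibble with `chrom`, `pos`, `rna_depth`, `rna_mac`.
#' @export
simulate_rna <- function(dna_calls, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(dna_calls, c("chrom", "pos", "tumor_maf"), "dna_calls")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "rna"))
  n <- nrow(dna_calls)
  depth <- vec_nb(rep(config$rna_mean_depth, n), config$dispersion)
  tibble(chrom = dna_calls$chrom, pos = dna_calls$pos,
         rna_depth = depth,
         rna_mac = rbinom(n, depth, dna_calls$tumor_maf))
}
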