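#' Run a pipeline stage with provenance
#'
#' Dispatcher behind the command-line interface. Each stage reads its
#' tabular inputs, runs the corresponding package functions with the
#' assay's default thresholds (overridable via `params`), and writes
#' deterministic outputs plus a JSON run manifest recording parameters,
#' seed and input checksums. Reruns with identical inputs and seed give
#' byte-identical outputs. Inputs are never modified.
#'
#' Stages: `qc` (coverage report), `call-snv` (site test + four-filter
#' chain, optional curated-list refinement; minimal VCF + TSV),
#' `smg` (gene burden test), `cnv` (flexible windows, CNR, centering,
#' HMM segmentation; SEG + window TSV), `emac` (RNA-seq validation
#' strata), `simulate` (synthetic fixture set + truth JSON).
#'
#' @param stage One of `"qc"`, `"call-snv"`, `"smg"`, `"cnv"`,
#'   `"emac"`, `"simulate"`.
#' @param inputs Named list of input file paths (stage-dependent; see
#'   Details).
#' @param out_dir Output directory, created if needed.
#' @param seed Master seed for all stochastic steps.
#' @param params Named list overriding stage parameters (defaults:
#'   `min_mapq` 5, `callq` 20, `alpha` 0.001, `min_maf` 0.005,
#'   `min_mac` 5, `min_log2or` 4, `fdr` 0.05, `min_depth_per_sample`
#'   20, `min_window` 20000, `max_states` 5, `decay_length` 1e6,
#'   `neutral_band` 0.2, `read_length` 100).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_stage <- function(stage, inputs = list(), out_dir = ".", seed = 1L,
                      params = list()) {
  stages <- c("qc", "call-snv", "smg", "cnv", "emac", "simulate")
  if (!stage %in% stages) {
    abort(sprintf("unknown subcommand '%s' (expected one of: %s)",
                  stage, paste(stages, collapse = ", ")))
  }
  defaults <- list(
    min_mapq = 5, callq = 20, callq_run = 5, alpha = 0.001, min_maf = 0.005,
    min_mac = 5, min_log2or = 4, fdr = 0.05, min_depth_per_sample = 20,
    min_window = 20000, max_states = 5, decay_length = 1e6,
    neutral_band = 0.2, read_length = 100, n_pool_samples = 8,
    sample_id = "SAMPLE", subsample_fraction = 1
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, params)
  if (p$min_maf < 0 || p$alpha <= 0 || p$alpha > 1 || p$min_mac < 0) {
    abort("parameter out of range")
  }
  for (f in unlist(inputs)) {
    if (is.character(f) && !file.exists(f)) {
      abort(sprintf("unreadable input: %s", f))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  result <- switch(stage,
    "qc" = stage_qc(inputs, out_dir, p),
    "call-snv" = stage_call_snv(inputs, out_dir, p),
    "smg" = stage_smg(inputs, out_dir, p),
    "cnv" = stage_cnv(inputs, out_dir, seed, p),
    "emac" = stage_emac(inputs, out_dir, p),
    "simulate" = stage_simulate(inputs, out_dir, seed, p)
  )
  manifest <- list(
    stage = stage,
    seed = seed,
    parameters = p[order(names(p))],
    inputs = lapply(inputs, function(f) {
      if (is.character(f) && file.exists(f)) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      } else f
    }),
    outputs = result$outputs,
    counts = result$counts
  )
  manifest_path <- file.path(out_dir, sprintf("%s_manifest.json",
                                              gsub("-", "_", stage)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}

provenance_header <- function(stage, p, seed) {
  c(sprintf("# stage: %s", stage),
    sprintf("# seed: %d", seed),
    sprintf("# %s", paste(sprintf("%s=%s", names(p),
                                  vapply(p, format, character(1))),
                          collapse = " ")))
}

stage_qc <- function(inputs, out_dir, p) {
  depth <- readr::read_tsv(inputs$depth, show_col_types = FALSE,
                           progress = FALSE)
  targets <- read_bed(inputs$targets)
  rep <- coverage_report(depth, targets, read_length = p$read_length)
  out <- file.path(out_dir, "coverage_qc.tsv")
  readr::write_tsv(rep$breadth, out, progress = FALSE)
  json_out <- file.path(out_dir, "coverage_qc.json")
  jsonlite::write_json(list(
    on_target_rate = rep$on_target_rate,
    breadth = rep$breadth,
    median_rpkm = rep$median_rpkm,
    summary = rep$summary
  ), json_out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(report = rep, outputs = c(out, json_out),
       counts = list(targets = nrow(targets)))
}

stage_call_snv <- function(inputs, out_dir, p) {
  counts <- read_counts_table(inputs$counts)
  calls <- test_sites(counts)
  n_skipped <- sum(!is.na(calls$skipped_reason))
  calls <- filter_calls(calls, alpha = p$alpha, min_maf = p$min_maf,
                        min_mac = p$min_mac, min_log2or = p$min_log2or)
  n_tested <- attr(calls, "filters")$n_tested
  refined <- NULL
  if (!is.null(inputs$positions)) {
    positions <- read_position_list(inputs$positions)
    refined <- refine_by_list(filter(calls, .data$pass), positions)
  }
  vcf <- file.path(out_dir, "calls.vcf")
  write_vcf_minimal(calls, vcf, sample_id = p$sample_id)
  tsv <- file.path(out_dir, "calls.tsv")
  hdr <- c(provenance_header(
    "call-snv", p[c("alpha", "min_maf", "min_mac", "min_log2or")], 0L),
    sprintf("# n_tested=%d n_skipped=%d", n_tested, n_skipped))
  writeLines(hdr, tsv)
  readr::write_tsv(calls, tsv, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  outs <- c(vcf, tsv)
  if (!is.null(refined)) {
    rtsv <- file.path(out_dir, "calls_refined.tsv")
    readr::write_tsv(refined, rtsv, progress = FALSE)
    outs <- c(outs, rtsv)
  }
  counts_out <- list(sites = nrow(calls), tested = n_tested,
                     skipped = n_skipped, passing = sum(calls$pass))
  if (!is.null(refined)) counts_out$refined <- nrow(refined)
  list(calls = calls, refined = refined, outputs = outs,
       counts = counts_out)
}

stage_smg <- function(inputs, out_dir, p) {
  genes <- readr::read_tsv(inputs$genes, show_col_types = FALSE,
                           progress = FALSE)
  fit <- smg_test(genes, fdr = p$fdr)
  out <- file.path(out_dir, "smg.tsv")
  readr::write_tsv(tidy(fit), out, progress = FALSE)
  list(fit = fit, outputs = out,
       counts = list(genes = nrow(genes),
                     significant = sum(tidy(fit)$significant)))
}

stage_cnv <- function(inputs, out_dir, seed, p) {
  tumor <- readr::read_tsv(inputs$tumor_depth, show_col_types = FALSE,
                           progress = FALSE)
  normal <- readr::read_tsv(inputs$normal_depth, show_col_types = FALSE,
                            progress = FALSE)
  windows <- build_windows(normal, n_pool_samples = p$n_pool_samples,
                           min_depth_per_sample = p$min_depth_per_sample,
                           min_width = p$min_window)
  windows <- count_in_windows(windows, tumor, "tumor_count")
  windows <- count_in_windows(windows, normal, "normal_count")
  profile <- compute_cnr(windows, windows$tumor_count, windows$normal_count)
  profile <- center_cnr(profile)
  segmentation <- segment_hmm(profile, max_states = p$max_states,
                              decay_length = p$decay_length, seed = seed,
                              neutral_band = p$neutral_band)
  seg_path <- file.path(out_dir, "segments.seg")
  write_seg(tidy(segmentation), p$sample_id, seg_path)
  win_path <- file.path(out_dir, "windows_cnr.tsv")
  readr::write_tsv(
    select(as_tibble(profile), "chrom", "start", "end",
           "tumor_count", "normal_count", "cnr", "masked"),
    win_path, progress = FALSE)
  list(profile = profile, segmentation = segmentation,
       outputs = c(seg_path, win_path),
       counts = list(windows = nrow(profile),
                     masked = sum(profile$masked),
                     segments = nrow(tidy(segmentation))))
}

stage_emac <- function(inputs, out_dir, p) {
  calls <- readr::read_tsv(inputs$calls, show_col_types = FALSE,
                           progress = FALSE)
  rna <- readr::read_tsv(inputs$rna, show_col_types = FALSE,
                         progress = FALSE)
  records <- emac_records(calls, rna)
  rates <- confirmation_rates(records)
  rec_path <- file.path(out_dir, "emac_records.tsv")
  readr::write_tsv(records, rec_path, progress = FALSE)
  rate_path <- file.path(out_dir, "emac_rates.tsv")
  readr::write_tsv(rates, rate_path, progress = FALSE)
  list(records = records, rates = rates,
       outputs = c(rec_path, rate_path),
       counts = list(records = nrow(records),
                     covered = sum(records$covered),
                     confirmed = sum(records$confirmed)))
}

stage_simulate <- function(inputs, out_dir, seed, p) {
  cfg_over <- if (!is.null(inputs$config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a simulate config file requires the yaml package")
    }
    yaml::read_yaml(inputs$config)
  } else list()
  cfg_over$seed <- seed
  cfg <- do.call(sim_config, cfg_over)
  tracks <- simulate_depth(cfg)
  pileups <- simulate_pileups(cfg)
  paths <- c(
    tumor_depth = file.path(out_dir, "sim_tumor_depth.tsv"),
    normal_depth = file.path(out_dir, "sim_normal_depth.tsv"),
    counts = file.path(out_dir, "sim_counts.tsv"),
    panel = file.path(out_dir, "sim_panel.bed"),
    truth = file.path(out_dir, "sim_truth.json")
  )
  readr::write_tsv(tracks$tumor, paths[["tumor_depth"]], progress = FALSE)
  readr::write_tsv(tracks$normal, paths[["normal_depth"]], progress = FALSE)
  write_counts_table(pileups, paths[["counts"]])
  write_bed(cfg$panel, paths[["panel"]])
  jsonlite::write_json(list(
    seed = cfg$seed,
    planted_cnv = cfg$planted_cnv,
    planted_snv = cfg$planted_snv,
    error_rate = cfg$error_rate,
    n_pool_samples = cfg$n_pool_samples,
    mean_depth = cfg$mean_depth,
    on_target_rate_true = cfg$on_target_rate_true
  ), paths[["truth"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(config = cfg, outputs = as.list(paths),
       counts = list(sites = nrow(pileups),
                     panel_regions = nrow(cfg$panel)))
}
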