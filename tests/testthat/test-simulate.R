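test_that("depth simulation is seed-reproducible and respects planted CNV", {
  cfg <- sim_config(seed = 4, n_chroms = 1, chrom_length = 100000,
                    planted_cnv = tibble::tibble(chrom = "chr1",
                                                 start = 20001L,
                                                 end = 60000L,
                                                 log2_ratio = -1))
  a <- simulate_depth(cfg)
  b <- simulate_depth(cfg)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$normal, b$normal)

  # single-copy loss halves the mean tumor depth over the event
  inside <- a$tumor$pos >= 20001 & a$tumor$pos <= 60000
  on <- a$truth$on_target
  ratio_in <- mean(a$tumor$depth[inside & !on]) /
    (mean(a$normal$depth[inside & !on]) / cfg$n_pool_samples)
  ratio_out <- mean(a$tumor$depth[!inside & !on]) /
    (mean(a$normal$depth[!inside & !on]) / cfg$n_pool_samples)
  expect_equal(ratio_in, 0.5, tolerance = 0.1)
  expect_equal(ratio_out, 1, tolerance = 0.1)
})

test_that("a null simulation gives a near-zero genome-wide median CNR", {
  cfg <- sim_config(seed = 14, n_chroms = 1, chrom_length = 150000,
                    on_target_rate_true = 0.1)
  tr <- simulate_depth(cfg)
  w <- build_windows(tr$normal, n_pool_samples = cfg$n_pool_samples)
  w <- count_in_windows(w, tr$tumor, "tumor_count")
  w <- count_in_windows(w, tr$normal, "normal_count")
  prof <- compute_cnr(w, w$tumor_count, w$normal_count)
  expect_lt(abs(median(prof$cnr[!prof$masked])), 0.1)
  cent <- center_cnr(prof)
  expect_equal(median(cent$cnr[!cent$masked]), 0)
})

test_that("simulated on-target rate tracks the configured truth", {
  cfg <- sim_config(seed = 2, n_chroms = 1, chrom_length = 100000,
                    on_target_rate_true = 0.7)
  tr <- simulate_depth(cfg)
  on <- tr$truth$on_target
  got <- sum(tr$normal$depth[on]) / sum(tr$normal$depth)
  expect_equal(got, 0.7, tolerance = 0.03)
})

test_that("pileup simulation plants SNVs at the requested MAF", {
  snv <- tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L),
                        maf = c(0.2, 0.4))
  cfg <- sim_config(seed = 8, planted_snv = snv, n_null_sites = 200,
                    mean_depth = 500)
  pu <- simulate_pileups(cfg)
  expect_identical(pu, simulate_pileups(cfg))
  expect_equal(sum(pu$is_snv), 2)
  expect_equal(nrow(pu), 202)
  expect_true(all(pu$tumor_mac <= pu$tumor_depth))
  expect_true(all(pu$normal_mac <= pu$normal_depth))

  # planted MAF ~ 0.2 at depth ~ 500 -> MAC near 100 over replicates
  macs <- vapply(1:30, function(i) {
    cfg_i <- sim_config(seed = i, planted_snv = snv[1, ],
                        n_null_sites = 0, mean_depth = 500, dispersion = 0)
    simulate_pileups(cfg_i)$tumor_mac[1]
  }, numeric(1))
  expect_equal(mean(macs), 100, tolerance = 0.12)

  # pooled-normal depth is on the n_pool_samples x mean_depth scale
  expect_equal(mean(pu$normal_depth), cfg$n_pool_samples * cfg$mean_depth,
               tolerance = 0.1)

  # null-site mutant rate sits inside the configured error band
  null_rate <- sum(pu$normal_mac) / sum(pu$normal_depth)
  expect_gt(null_rate, 0.0005)
  expect_lt(null_rate, 0.004)
})

test_that("error-free simulation yields zero mutant reads at null sites", {
  cfg <- sim_config(seed = 3, error_rate = c(0, 0), n_null_sites = 300)
  pu <- simulate_pileups(cfg)
  expect_true(all(pu$tumor_mac == 0))
  expect_true(all(pu$normal_mac == 0))
})

test_that("config validation rejects out-of-bounds planted features", {
  expect_error(sim_config(planted_snv = tibble::tibble(
    chrom = "chr9", pos = 1L, maf = 0.1)), "chromosomes")
  expect_error(sim_config(error_rate = c(0.002, 0.001)))
  bad_panel <- tibble::tibble(chrom = "chr1", start = 1L, end = 10^7L,
                              gene_id = "X")
  expect_error(sim_config(panel = bad_panel), "bounds")
})

test_that("the simulate stage writes re-readable fixtures with truth", {
  out <- withr::local_tempdir()
  res <- run_stage("simulate", out_dir = out, seed = 99)
  counts <- read_counts_table(file.path(out, "sim_counts.tsv"))
  expect_gt(nrow(counts), 0)
  panel <- read_bed(file.path(out, "sim_panel.bed"))
  expect_equal(nrow(panel), nrow(res$config$panel))
  truth <- jsonlite::read_json(file.path(out, "sim_truth.json"))
  expect_equal(truth$seed, 99)
  expect_equal(truth$n_pool_samples, res$config$n_pool_samples)
})
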