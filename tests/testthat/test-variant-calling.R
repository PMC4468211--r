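test_that("site test matches closed-form LRT and OR arithmetic", {
  st <- site_test(1000, 50, 10000, 1)
  # frozen from the closed-form deviance / odds-ratio computation
  expect_equal(st$log2_or, 9.039641, tolerance = 1e-6)
  expect_equal(st$p_raw, 8.743993e-53, tolerance = 1e-4)
  expect_lt(st$p_raw, 1e-10)
  expect_gte(st$log2_or, 4)
})

test_that("site test handles no-evidence, equal-rate and zero-depth sites", {
  # no mutant evidence -> p = 1
  none <- test_sites(site_row(tumor_depth = 500, tumor_mac = 0,
                              normal_depth = 4000, normal_mac = 3))
  expect_equal(none$p_raw, 1)

  # equal rates -> log2 OR ~ 0, p >= 0.5
  eq <- test_sites(site_row(tumor_depth = 1000, tumor_mac = 10,
                            normal_depth = 10000, normal_mac = 100))
  expect_equal(eq$log2_or, 0, tolerance = 0.02)
  expect_gte(eq$p_raw, 0.5)

  # zero depth -> skipped with a reason, and scalar form errors
  z <- test_sites(site_row(tumor_depth = 0, tumor_mac = 0,
                           normal_depth = 4000, normal_mac = 0))
  expect_true(is.na(z$p_raw))
  expect_match(z$skipped_reason, "zero depth")
  expect_error(site_test(0, 0, 100, 0), "zero depth")

  # zero-cell sites get the continuity-corrected, finite OR
  zc <- test_sites(site_row(tumor_depth = 100, tumor_mac = 5,
                            normal_depth = 10000, normal_mac = 0))
  expect_true(is.finite(zc$log2_or))
  expect_equal(zc$log2_or, log2((5.5 / 95.5) / (0.5 / 10000.5)))
})

test_that("site-test p-values track an exact binomial tail oracle", {
  # oracle: P(X >= M_t) for X ~ Binom(D_t, pooled-normal rate), the
  # deep-pool limit of the contrast
  set.seed(71)
  n <- 1000
  dn <- sample(2000:10000, n, replace = TRUE)
  mn <- pmax(1L, rbinom(n, dn, runif(n, 0.001, 0.005)))
  dt <- sample(20:100, n, replace = TRUE)
  mt <- rbinom(n, dt, runif(n, 0.005, 0.05))
  res <- test_sites(tibble::tibble(tumor_depth = dt, tumor_mac = mt,
                                   normal_depth = dn, normal_mac = mn))
  oracle <- pbinom(mt - 1, dt, mn / dn, lower.tail = FALSE)
  sel <- res$p_raw < 0.5 & oracle > 0  # informative sites
  ratio <- log10(res$p_raw[sel]) - log10(oracle[sel])
  expect_gt(mean(abs(ratio) <= 1), 0.98)
  expect_lt(stats::median(abs(ratio)), 0.5)
})

test_that("the four filters apply inclusive thresholds", {
  call <- tibble::tibble(
    chrom = "chr1", pos = 1L,
    tumor_maf = 0.005, tumor_mac = 5,
    p_raw = 0.001 / 200, log2_or = 4
  )
  out <- filter_calls(call, n_tested = 200)
  expect_equal(out$p_bonf, 0.001)
  expect_true(out$pass)  # every threshold exactly at its boundary passes

  # MAC one below the cutoff fails only the MAC filter
  out2 <- filter_calls(dplyr::mutate(call, tumor_mac = 4), n_tested = 200)
  expect_false(out2$pass)
  expect_false(out2$pass_mac)
  expect_true(out2$pass_pbonf && out2$pass_maf && out2$pass_log2or)

  # log2 OR 4 is tumor odds >= 16x pooled-normal odds
  expect_equal(2^4, 16)
  or16 <- test_sites(site_row(tumor_depth = 1016, tumor_mac = 16,
                              normal_depth = 100100, normal_mac = 100))
  expect_equal(2^or16$log2_or, (16 / 1000) / (100 / 100000), tolerance = 1e-12)

  # Bonferroni denominator defaults to the number of tested sites
  two <- test_sites(site_row(pos = c(1L, 2L),
                             tumor_depth = c(1000, 0), tumor_mac = c(50, 0),
                             normal_depth = c(10000, 100), normal_mac = c(1, 0)))
  out3 <- filter_calls(two)
  expect_equal(attr(out3, "filters")$n_tested, 1)
})

test_that("curated-list refinement keeps only listed positions", {
  # toy single-exon region: 111 positions, 6 hotspot + 52 listed, 53 not
  region_pos <- 25398208:25398318
  hot <- 25398280:25398285
  listed <- c(hot, setdiff(region_pos, hot)[1:52])
  lst <- tibble::tibble(chrom = "chr12", pos = listed, kind = "SNV",
                        tier = "conservative")
  calls <- tibble::tibble(chrom = "chr12", pos = region_pos, p_raw = 1e-9)
  refined <- refine_by_list(calls, lst)
  expect_equal(nrow(refined), 58)
  expect_true(all(refined$pos %in% listed))
  expect_equal(unique(refined$tier), "conservative")
  expect_equal(nrow(dplyr::anti_join(calls, lst, by = c("chrom", "pos"))), 53)

  # refinement output is a subset; a superset list keeps at least as much
  expect_equal(nrow(refine_by_list(calls, lst[0, ])), 0)
  superset <- dplyr::bind_rows(lst, tibble::tibble(
    chrom = "chr12", pos = setdiff(region_pos, listed)[1:10],
    kind = "SNV", tier = "less_conservative"))
  expect_gte(nrow(refine_by_list(calls, superset)), nrow(refined))
})

test_that("leave-one-out pools aggregate all but the held-out normal", {
  set.seed(9)
  normals <- lapply(1:24, function(i) {
    tibble::tibble(chrom = "chr1", pos = 1:50,
                   depth = rpois(50, 100), mac = rbinom(50, 100, 0.002))
  })
  pool <- build_loo_pool(normals, held_out = 7)
  expect_equal(nrow(pool), 50)
  members <- normals[-7]
  expect_length(members, 23)
  expect_equal(pool$normal_depth,
               Reduce(`+`, lapply(members, function(x) x$depth)))
  expect_equal(pool$normal_mac,
               Reduce(`+`, lapply(members, function(x) x$mac)))

  # n = 2: the pool is exactly the other sample
  p2 <- build_loo_pool(normals[1:2], held_out = 1)
  expect_equal(p2$normal_depth, normals[[2]]$depth)
  expect_error(build_loo_pool(normals[1], 1), ">= 2")
})

test_that("pool subsampling is binomial thinning with a fixed seed", {
  pool <- tibble::tibble(chrom = "chr1", pos = 1:2000,
                         normal_depth = 10000L,
                         normal_mac = rbinom(2000, 10000, 0.002))
  expect_equal(subsample_pool(pool, 1), pool)  # identity at fraction 1

  half <- subsample_pool(pool, 0.5, seed = 4)
  expect_equal(half, subsample_pool(pool, 0.5, seed = 4))  # deterministic
  expect_true(all(half$normal_mac <= half$normal_depth))
  # mean thinned depth within 3 SD of fraction * original
  se <- sqrt(10000 * 0.25 / 2000)
  expect_lt(abs(mean(half$normal_depth) - 5000), 3 * se)
  expect_error(subsample_pool(pool, 0), "fraction")
})
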