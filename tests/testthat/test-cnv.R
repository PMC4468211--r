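test_that("uniform high coverage yields min-width windows tiling exactly", {
  # linear-scan oracle: depth ample everywhere, so every window closes
  # at the minimum width -> 5 windows of 20 kbp on a 100-kbp chromosome
  depth <- make_depth_track(list(chr1 = rep(30, 100000)))
  w <- build_windows(depth, n_pool_samples = 1,
                     min_depth_per_sample = 20, min_width = 20000)
  expect_equal(nrow(w), 5)
  expect_true(all(w$width == 20000))
  expect_equal(w$start, as.integer(seq(1, 80001, by = 20000)))
  expect_equal(w$end, w$start + 19999L)
})

test_that("a zero-coverage chromosome becomes one flagged window", {
  depth <- make_depth_track(list(chr1 = rep(30, 50000),
                                 chr2 = rep(0, 50000)))
  w <- build_windows(depth, n_pool_samples = 1, min_width = 20000)
  w2 <- w[w$chrom == "chr2", ]
  expect_equal(nrow(w2), 1)
  expect_true(w2$low_coverage)
  expect_equal(c(w2$start, w2$end), c(1L, 50000L))
  expect_false(any(w$low_coverage[w$chrom == "chr1"]))
})

test_that("windows tile chromosomes and non-terminal windows meet criteria", {
  set.seed(41)
  for (i in 1:100) {
    L <- sample(60000:150000, 1)
    mu <- runif(1, 5, 120)
    d <- rnbinom(L, mu = mu, size = 2)
    thr <- 20; npool <- sample(1:3, 1)
    w <- build_windows(make_depth_track(list(chrA = d)),
                       n_pool_samples = npool,
                       min_depth_per_sample = thr, min_width = 20000)
    # exact tiling: union is the covered span, pairwise disjoint
    expect_equal(w$start[1], 1L)
    expect_equal(w$end[nrow(w)], L)
    if (nrow(w) > 1) {
      expect_equal(w$start[-1], w$end[-nrow(w)] + 1L)
      # non-terminal windows satisfy both restrictions
      nt <- seq_len(nrow(w) - 1)
      expect_true(all(w$width[nt] >= 20000))
      expect_true(all(w$mean_depth[nt] >= thr * npool - 1e-9))
    }
  }
})

test_that("shrinking the minimum width never widens any window", {
  set.seed(6)
  d <- rnbinom(120000, mu = 25, size = 2)
  track <- make_depth_track(list(chr1 = d))
  w_big <- build_windows(track, 1, min_depth_per_sample = 20,
                         min_width = 30000)
  w_small <- build_windows(track, 1, min_depth_per_sample = 20,
                           min_width = 10000)
  expect_lte(max(w_small$width), max(w_big$width))
  expect_gte(nrow(w_small), nrow(w_big))
})

test_that("per-window counting matches direct interval sums", {
  set.seed(8)
  d <- rpois(5000, 10)
  track <- make_depth_track(list(chr1 = d))
  w <- tibble::tibble(chrom = "chr1", start = c(1L, 1001L, 4001L),
                      end = c(1000L, 4000L, 5000L))
  out <- count_in_windows(w, track, "count")
  expect_equal(out$count,
               c(sum(d[1:1000]), sum(d[1001:4000]), sum(d[4001:5000])))
})

test_that("copy-number ratios follow the library-normalized log2 formula", {
  w <- tibble::tibble(chrom = "chr1", start = c(1L, 101L, 201L),
                      end = c(100L, 200L, 300L))
  prof <- compute_cnr(w, tumor_counts = c(200, 100, 0),
                      normal_counts = c(50, 100, 0),
                      tumor_lib = 1e6, normal_lib = 1e6)
  expect_equal(prof$cnr[1], 2)           # log2(4)
  expect_equal(prof$cnr[2], 0)           # equal normalized counts
  expect_true(prof$masked[3])            # zero normal -> masked
  expect_true(is.na(prof$cnr[3]))

  # invariance under joint rescaling of a library's counts and size
  prof2 <- compute_cnr(w, c(400, 200, 0), c(50, 100, 0),
                       tumor_lib = 2e6, normal_lib = 1e6)
  expect_equal(prof2$cnr, prof$cnr)

  expect_error(compute_cnr(w, c(1, 1, 1), c(0, 0, 0), normal_lib = 1),
               "masked")
})

test_that("median centering zeroes the genome median and is idempotent", {
  w <- tibble::tibble(chrom = "chr1", start = seq(1, 901, 100),
                      end = seq(100, 1000, 100))
  prof <- compute_cnr(w, tumor_counts = rep(162, 10),
                      normal_counts = rep(100, 10),
                      tumor_lib = 1e5, normal_lib = 1e5)
  expect_equal(unique(round(prof$cnr, 4)), round(log2(1.62), 4))
  cent <- center_cnr(prof)
  expect_equal(cent$cnr, rep(0, 10))     # constant profile -> all zero
  expect_equal(median(cent$cnr[!cent$masked]), 0)
  again <- center_cnr(cent)
  expect_equal(again$cnr, cent$cnr)      # idempotent
  expect_true(attr(cent, "centered"))
})

test_that("gene-level tracks recover planted exon losses at 1-bp resolution", {
  set.seed(19)
  L <- 6000
  exons <- tibble::tibble(chrom = "chr1",
                          start = c(501L, 2001L, 4001L),
                          end = c(900L, 2400L, 4400L),
                          gene_id = "GENE1")
  normal <- rep(200, L)
  tumor <- rep(200, L)
  tumor[4001:4400] <- 100  # heterozygous loss over exon 3 only
  track_n <- make_depth_track(list(chr1 = normal))
  track_t <- make_depth_track(list(chr1 = tumor))
  cnv <- gene_level_cnv(exons, track_t, track_n,
                        tumor_lib = 1e6, normal_lib = 1e6)
  ex3 <- cnv$pos >= 4001 & cnv$pos <= 4400
  expect_equal(unique(cnv$log2_ratio[ex3]), -1)
  expect_equal(unique(cnv$log2_ratio[!ex3]), 0)
  expect_equal(nrow(cnv), sum(exons$end - exons$start + 1))

  # masking: zero-normal bases are absent from the output
  normal[501:510] <- 0
  cnv2 <- gene_level_cnv(exons, track_t,
                         make_depth_track(list(chr1 = normal)),
                         tumor_lib = 1e6, normal_lib = 1e6)
  expect_false(any(cnv2$pos %in% 501:510))
  expect_error(gene_level_cnv(exons[0, ], track_t, track_n), "non-empty")
})

test_that("tumor identical to normal gives a flat zero gene track", {
  exons <- tibble::tibble(chrom = "chr1", start = 101L, end = 400L,
                          gene_id = "G")
  track <- make_depth_track(list(chr1 = rep(50, 1000)))
  cnv <- gene_level_cnv(exons, track, track)
  expect_equal(unique(cnv$log2_ratio), 0)
})
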