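# Shared fixture builders; everything is generated in code at test time.

# Contiguous per-base depth track for one or more chromosomes.
make_depth_track <- function(depths_by_chrom) {
  dplyr::bind_rows(lapply(names(depths_by_chrom), function(ch) {
    d <- depths_by_chrom[[ch]]
    tibble::tibble(chrom = ch, pos = seq_along(d), depth = d)
  }))
}

# A centered cnr_profile built directly from window values (bypasses
# counting); windows are contiguous `width`-sized tiles on one chromosome.
make_profile <- function(cnr, width = 20000, chrom = "chr1") {
  n <- length(cnr)
  windows <- tibble::tibble(
    chrom = chrom,
    start = as.integer((seq_len(n) - 1) * width + 1),
    end = as.integer(seq_len(n) * width)
  )
  # reconstruct counts consistent with the requested cnr values
  normal <- rep(1000, n)
  tumor <- 1000 * 2^cnr
  prof <- compute_cnr(windows, tumor, normal,
                      tumor_lib = sum(tumor), normal_lib = sum(normal))
  # overwrite with the exact requested values, mark as centered
  prof$cnr <- cnr
  attr(prof, "centered") <- TRUE
  prof
}

# Count-table row constructor for site-level tests.
site_row <- function(chrom = "chr1", pos = 100, tumor_depth, tumor_mac,
                     normal_depth, normal_mac) {
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T",
                 tumor_depth = tumor_depth, tumor_mac = tumor_mac,
                 normal_depth = normal_depth, normal_mac = normal_mac)
}
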