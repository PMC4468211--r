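Package: panelscope
Title: Coverage QC, Somatic Variant Filtering and Read-Depth Copy Number
    for Targeted Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for tumor-only targeted panel sequencing
    (TPS) with a pooled unmatched normal as control. Implements panel
    coverage quality control (depth, breadth of coverage, on-target rate,
    RPKM, order-statistic median confidence intervals), site-level SNV
    significance testing of tumor versus pooled normal with a one-sided
    binomial likelihood-ratio test and the four-filter call chain
    (Bonferroni-adjusted p-value, mutant allele frequency, mutant allele
    count, log2 odds ratio), hotspot-list refinement, a gene-length
    adjusted significantly-mutated-gene binomial test with FDR control,
    RNA-seq cross-validation via expected mutant allele counts (EMAC),
    and read-depth copy-number detection with restriction-imposed
    flexible windowing, library-normalized log2 copy-number ratios and
    heterogeneous hidden Markov model segmentation. A seeded simulator
    generates panels, depth tracks with planted copy-number events,
    tumor and pooled-normal pileups, and RNA-seq counts so that every
    component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml
Config/testthat/edition: 3
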