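---
title: "Methods: coverage QC, tumor-only SNV filtering and read-depth CNV for targeted panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage QC, tumor-only SNV filtering and read-depth CNV for targeted panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscope)
library(dplyr)
```

panelscope analyzes tumor-only targeted panel sequencing (TPS): a
capture panel of a few hundred cancer genes sequenced deeply in tumor
tissue, with an *unmatched pooled normal* — aggregated sequencing of
several normal tissues — standing in for the missing same-patient
germline. This vignette is the package's account of its statistical
models, the parameters that matter, and the choices made where the
design was genuinely open. All coordinates inside the package are
1-based and inclusive; BED input/output is converted at the boundary.

## Read filtering and coverage QC

Two read-level contracts precede everything else. Reads with mapping
quality below 5 (Phred; under ~70% mapping accuracy) are removed
(`filter_by_mapq()`). Read ends are trimmed while a terminal run of
consecutive bases has mean base-call quality at or below 20
(`trim_by_callq()`). The run length of that rule is not a settled
convention; we default to 5 bases, repeat trimming until no terminal
window qualifies, and drop a read trimmed below one run length. Both
the run length and the threshold are arguments, so a single-pass or
longer-window variant is a parameter change, not a code change.

Panel QC (`coverage_report()`) uses standard definitions: *depth* is
the number of reads covering a base; *breadth of coverage* at t is the
fraction of targeted bases with depth ≥ t (reported at 1x, 20x, 50x,
100x; non-increasing in t by construction); the *on-target rate* is
counted in bases — aligned bases inside targets over all aligned bases
— matching how capture efficiency is usually quoted for panels; *RPKM*
is reads per region-kilobase per million mapped reads. The median RPKM
carries an approximate 95% confidence interval from order statistics at
ranks `ceiling(n/2 ± z√n/2)` (the usual normal approximation to the
binomial ranks of the median), clipped to the sample — exact coverage
is approximate, which the Monte-Carlo test in the suite quantifies
(~93–98% across 1,000 replicates at n = 100).

## Site-level SNV test against the pooled normal

At each site we observe tumor depth $D_t$ with mutant allele count
$M_t$, and pooled-normal depth $D_n$ with $M_n$. The test is a
one-sided binomial likelihood-ratio test of

$$H_0: p_t = p_n \qquad \text{vs} \qquad H_1: p_t > p_n,$$

with the deviance referred to $\tfrac12\chi^2_1$ (halved for
one-sidedness) and $p = 1$ whenever $\hat p_t \le \hat p_n$. The
binomial rather than beta-binomial likelihood is the default: no
dispersion estimate is available for the pooled control, and the
beta-binomial reduces to it in the well-mixed limit; the test function
is the single extension point if overdispersion must be modelled. On
small-count sites the p-values track the exact binomial tail with the
pooled rate plugged in (the deep-pool limit) to within an order of
magnitude; far out in the tail (p below ~1e-12) any asymptotic test
departs from the exact tail, which is irrelevant at the 0.001
significance threshold used downstream.

The effect size is the log2 odds ratio
$\log_2\frac{M_t/(D_t-M_t)}{M_n/(D_n-M_n)}$. A continuity constant of
0.5 is added to all four cells *only when some cell is zero*, keeping
the statistic finite for the motivating case of a mutation entirely
absent from the pooled normal while leaving non-degenerate sites exact.

A site is called significant when **all four** filters pass, thresholds
inclusive:

| filter | default | meaning |
|---|---|---|
| Bonferroni-adjusted p | ≤ 0.001 | `p_raw × n_tested`, capped at 1 |
| tumor MAF | ≥ 0.005 | at least 2× above the 0.001–0.002 sequencing error |
| tumor MAC | ≥ 5 | minimum mutant read support |
| log2 OR | ≥ 4 | tumor mutant odds ≥ 16× the pooled normal |

The Bonferroni denominator is the number of sites actually tested in
the run (per-run rather than cohort-wide — the natural choice when each
tumor is tested against its own pool; it is logged in the output header
and settable). Calls can then be *refined* against curated position
lists — an expert-curated "conservative" tier or a broader
database-derived "less-conservative" tier — consumed as plain
chrom/pos/kind/tier tables; refinement is a pure intersection, so its
output is always a subset and monotone in the list.

For cohorts with matched normals, `build_loo_pool()` forms the
leave-one-out pool (all normals except the sample under test) and
`subsample_pool()` thins it binomially to a library size comparable to
one tumor; thinning mutant and reference reads independently preserves
`mac ≤ depth` and the expected fraction exactly.

## Significantly mutated genes

Gene-level burden is tested against the cohort background rate with a
gene-length adjustment: every tested base in every sample is one
Bernoulli trial, so gene $g$ with tested length $L_g$ in $S$ samples
contributes $L_gS$ trials. With $\hat r = \sum_g k_g / \sum_g L_gS$ the
pooled background rate, the p-value is the exact upper binomial tail
$P(X \ge k_g)$, $X \sim \mathrm{Bin}(L_gS, \hat r)$, and genes are
reported significant at Benjamini–Hochberg FDR ≤ 0.05 (the standard
procedure when only "FDR" is specified). Estimating $\hat r$ from the
cohort itself makes the planted gene's own mutations inflate the
background slightly — a conservative bias that the single-gene recovery
test shows is immaterial at realistic burdens.

## RNA-seq cross-validation (EMAC)

A DNA call with MAF $f$ at a site with RNA-seq depth $d$ has *expected
mutant allele count* $E = d \times f$. A call is *covered* with ≥ 1 RNA
read and *confirmed* when covered with at least one mutant RNA read —
the minimal faithful criterion given that confirmation is otherwise
delegated to external RNA callers; the mutant-read threshold is an
argument. `confirmation_rates()` reports the strata E ≥ 1, 2, 3 and the
E < 1 remainder; under the binomial model the confirmation probability
at a site is $1-(1-f)^d$, which makes the stratified rate increase with
E — the package's simulations reproduce that shape (e.g. ~94% at E ≥ 1
versus ~54% below E = 1 at seed 1).

## Copy number from read depth

TPS coverage is deep on targets and thin but genome-wide off target;
both contribute to copy number (off-target "background" reads are used
here and only here — never for SNV calling). The pipeline is:

1. **Restriction-imposed flexible windows** (`build_windows()`): a
   left-to-right scan closes a window at the first base where the mean
   per-base pooled-normal depth reaches `min_depth_per_sample ×
   n_pool_samples` (default 20x per pool member) *and* the window is at
   least `min_width` (default 20 kbp) wide. The depth restriction is
   interpreted as mean per-base depth: on a depth track, accumulated
   read count × read length / width *is* the mean depth, so the read
   length drops out. A terminal remainder failing either restriction is
   merged into the previous window, so windows tile each chromosome
   exactly and all non-terminal windows satisfy both restrictions; a
   zero-coverage chromosome yields one flagged window excluded from
   segmentation.
2. **CNR** (`compute_cnr()`): $\mathrm{cnr}_w = \log_2\frac{t_w/T}{n_w/N}$
   with library sizes $T, N$; windows with zero pooled-normal count are
   masked. Invariant under joint rescaling of a library's counts and
   size.
3. **Median centering** (`center_cnr()`): the genome-wide median over
   *all unmasked windows* (autosome-only centering was the other
   option; with a simulated genome there is no sex-chromosome asymmetry
   to motivate it) is subtracted so neutral regions sit at zero.
   Idempotent by construction.
4. **Heterogeneous HMM segmentation** (`segment_hmm()`): per
   chromosome, a Gaussian-emission HMM whose transition kernel depends
   on inter-window distance d: with probability
   $\rho(d)=1-e^{-d/\lambda}$ the chain redraws its state uniformly, so
   the probability of leaving the current state is
   $\rho(d)(K-1)/K$ — near zero between dense adjacent windows,
   approaching the uniform limit across megabase gaps. The distance
   scale $\lambda$ defaults to 1 Mbp, giving ~0.99 self-transition
   between 20-kbp-spaced windows. State means and a common emission
   variance are fitted by EM (transitions are structural, not
   re-estimated); K is chosen by BIC over 1..`max_states` (default 5)
   with parameter count K + 1; the Viterbi path is collapsed into
   segments. Segments are labelled loss/neutral/gain against a ±0.2
   CNR neutral band — a reporting convention, not part of the fit.
5. **Gene-level tracks** (`gene_level_cnv()`): per-base log2 ratios over
   a gene's exons at 1-bp resolution, masked where the pooled normal
   has zero depth — the view in which partial, single-exon events are
   visible below window resolution.

Numerical choices: EM runs at most 100 iterations to a relative
log-likelihood tolerance of 1e-6, initialized at state-count quantiles
of the data with a small seeded jitter; the emission standard deviation
is floored at 1e-3 to prevent degenerate single-window states; if EM
fails to converge at the BIC-chosen K, the largest smaller converged K
is used and a warning raised. Likelihood scaling (not log-space
arithmetic) is used in the forward–backward pass; emission densities
are floored at 1e-300. Identical inputs and seed give identical SEG
output, byte for byte.

## The simulator and what it does (not) emulate

`sim_config()` + `simulate_depth()` / `simulate_pileups()` /
`simulate_rna()` generate everything the other modules consume, with a
serialized truth record. Defaults are the assay's study conditions: a
pooled normal of 8 samples; ~70% of aligned bases on target; mean
on-target depth 300x per sample (deep panel coverage consistent with
nearly all targeted bases above 50–100x); per-site sequencing error
uniform in 0.001–0.002; negative-binomial depth with dispersion 0.1
(variance μ + 0.1μ²) to emulate capture unevenness rather than Poisson
regularity; RNA-seq mean depth 20, reflecting that RNA validation
operates at far lower depth than DNA — many sites fall below 5 reads,
which is what makes the E < 1 stratum populated. Planted copy-number
events multiply the tumor mean by $2^{\text{log2 ratio}}$; planted SNVs
draw tumor mutant counts at the planted MAF.

The simulator draws each base and site independently: it does not model
GC-dependent capture bias, correlated errors, mappability, tumor purity
or subclonal structure, indels, or read-level artifacts. Passing tests
therefore demonstrate that the algorithms recover what their models
assume, not that those models absorb every failure mode of real FFPE
sequencing — the filters' robustness to, e.g., strand-biased artifacts
is out of scope by design.

Problem sizes used by the test-suite and acceptance computations are
chosen to keep every run deterministic and fast while leaving no
estimate starved: 10⁵ null sites for type-I error, 400 planted SNVs for
power, 100 replicates for the SMG and HMM recovery rates, 100 random
tracks for the windowing invariants, chromosomes of 150–300 kbp for
end-to-end runs.

## Known limitations

- The site test treats the pooled normal as a single homogeneous
  library; donor-specific germline variants in the pool are not
  modelled (they inflate $M_n$ and thus make the test conservative at
  those sites).
- Window resolution bounds breakpoint accuracy; the HMM reports
  breakpoints at window granularity only, and gene-level tracks are the
  intended tool below that scale.
- The SMG trial count $L_gS$ assumes every tested base is callable in
  every sample; sample-specific callability masks would refine it.
- Indels are consumed only through curated position lists; indel
  calling itself is delegated to external tools.
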