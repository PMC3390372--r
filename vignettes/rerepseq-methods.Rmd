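---
title: "Methods: detecting heterochromatic re-replication and TE derepression"
author: "rerepseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting heterochromatic re-replication and TE derepression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerepseq)
```

# The problem

DNA replication origins must fire once per cell cycle. When that
control fails in heterochromatin — in *Arabidopsis*, the
pericentromeric, TE-dense compartment marked by H3K9me2 and dense DNA
methylation — the re-replicated chromatin acquires extra copies that
are directly visible as a localized excess of sequencing coverage in
mutant vs wild-type genomic DNA libraries, as a broadened 8C peak in
flow cytometry of endoreduplicated nuclei, and sometimes as
transcriptional reactivation of resident transposons in RNA-seq.
`rerepseq` implements the corresponding callers and summaries as a
reusable, tested pipeline, together with a synthetic-data generator
that plants known truth for validation.

# The re-replication caller

The caller consumes *deduplicated uniquely-mapped read placements*:
each read is reduced to its 5'-most aligned base, and reads sharing
(chromosome, 5' position, strand) are collapsed to one — the standard
single-end PCR-duplicate rule. Strand is part of the identity by
default because opposite-strand reads at one coordinate are distinct
fragments; `dedup_placements(ignore_strand = TRUE)` gives the stricter
reading.

1. **Binning.** The genome is tiled into 100-bp bins; a read belongs
   to the bin containing its 5' position (reads are counted, not
   per-base coverage, so fragment length is irrelevant).
2. **Scores.** With `M` the post-dedup library size in millions, each
   bin count `n` becomes `(n + c)/0.1 kb/M`, reads per kb per million
   with pseudocount `c = M/10`. The pseudocount keeps every score
   positive (an empty bin scores exactly 1 regardless of depth) so the
   log2 ratio below is finite everywhere. For libraries of 68 and 53
   million uniquely mapping reads, `pseudocount()` gives 6.8 and 5.3.
3. **Ratio and windows.** The per-bin log2(mutant/wild-type) score
   ratio is averaged over 1-kb windows stepped 500 bp. The window
   value is the arithmetic mean of its ten bin ratios (ratio first,
   then window aggregation); a final partial window is dropped so all
   windows have equal length and the Z population is homogeneous.
4. **Z-scores and calling.** Window values are standardized against
   the mean and standard deviation of *all* windows. Standardization
   is genome-wide by default (`per_chrom = TRUE` is available); no
   outlier trimming is applied. Windows with Z > 2 are kept and merged
   whenever separated by at most 500 bp; each merged region records
   its maximum Z and mean log2 ratio. If the window values are
   constant (sd = 0) all Z are defined as 0 and nothing is called — a
   flat track carries no signal.
5. **TE annotation.** A TE is re-replicating if it shares ≥ 1 bp with
   a called region. Intervals are 0-based half-open throughout, so
   touching intervals do not overlap; GFF3 input is converted from
   1-based closed coordinates on read.

Two caveats of the score scale are worth knowing when interpreting
`mean_log2`. Duplicate collapsing saturates dense bins (at 50 reads
per 100-bp bin roughly 12% of placements collide by chance), and a
mutant that re-replicates carries a larger library, which shifts the
normalization down everywhere; both compress the in-patch mean log2
ratio below the naive `log2(copy factor)`. The Z-score segmentation is
unaffected — standardization absorbs global scale — which is why the
caller recovers planted regions cleanly even though the plateau sits
below 1.0 for a 2-fold gain.

Accompanying statistics: `het_fraction()` (share of reads in a
heterochromatin region set), `compare_het_fractions()` (2×2 chi-square
with continuity correction, Fisher's exact fallback when any cell
is < 5; the method used is recorded in the result, since the choice of
test here is this package's, not inherited), `te_dna_density()` (reads
per kb of TE per million) and `ranksum_compare()` (two-sided Wilcoxon
rank-sum; for n + m ≤ 12 the null is enumerated exactly over all rank
splits, which handles ties exactly and returns p = 1 for identical
samples; larger samples fall back to `stats::wilcox.test`).
`chromosome_view()` reproduces the chromosome-scale presentation:
100-kb bin densities (reads/base/million), smoothed triangularly ten
times, either per sample or as a pseudocounted log2 ratio.

# The derepression caller

Expression is quantified as RPKM, `count/(length/1000)/(lib/10^6)`.
The calling rule, applied per replicate pair (replicate *i* of mutant
vs replicate *i* of wild type, batch-matched; other pairings can be
passed explicitly):

* **Zero replacement.** Within each sample, features with RPKM 0 are
  assigned the lowest non-zero RPKM of that sample, so ratios are
  finite. Counts are never zero-replaced — only the RPKM used for the
  fold change.
* **Fold change** is the ratio of zero-replaced RPKM values; the
  feature must exceed 4.
* **Significance.** Two-sided Fisher's exact test on the 2×2 table of
  feature count vs rest-of-library count in the two samples (exact
  tests need counts, not RPKM), Benjamini-Hochberg adjusted across
  features; the adjusted p must be below 0.01. The threshold is
  applied to adjusted values by default because the correction
  immediately precedes the cutoff in the procedure; `use_adjusted =
  FALSE` applies it to raw p-values instead. The test is two-sided;
  directionality is enforced by the fold-change criterion.
* **Intersection.** A feature is *derepressed* only if it passes in
  every replicate pair.

`overlap_sets()` compares called sets (e.g. re-replicated vs
derepressed TEs) with exact counts and an upper-tail hypergeometric
enrichment p; `family_composition()` tabulates TE superfamilies;
`browser_bins()` produces 20-bp RPKM tracks for browser-style figures.

# Methylation summaries

The level of a region is the pooled, coverage-weighted ratio
`Σ#C/Σ(#C+#T)` over its sites of one context (CG, CHG or CHH), both
strands pooled — a ratio of summed counts, not a mean of per-site
ratios (a per-site mode exists behind `per_site = TRUE`). Zero-coverage
bins are *missing*, never 0, are excluded from cross-feature means, and
split smoothing into independent runs. `chromosome_profile()` bins
levels at 100 kb (smoothed triangularly once) and `feature_metaplot()`
anchors levels on stranded features: flanks in fixed 100-bp bins, the
body rescaled to 20 fractional bins (each site contributes to the bin
containing its scaled coordinate), minus-strand features reversed so
the TSS is always on the left, smoothed triangularly three times.
Chromosome bin size, flank length and body-bin count are package
defaults, configurable per call.

# Signal numerics

* **Moving average** (`moving_average`): truncated edge windows —
  `out[i]` is the mean of the available neighbours within ± h — so no
  values are invented beyond chromosome ends.
* **Triangular smoothing** (`triangular_smooth`): interior points are
  convolved with (0.25, 0.5, 0.25) per iteration; the two endpoints,
  where the kernel is undefined, are copied unchanged. Copying keeps
  plots stable at boundaries and is exactly testable. Both operators
  are linear, preserve constants, and keep outputs within the input
  range.
* **Boundary metaplots** (`boundary_metaplot`): both boundaries of
  every region contribute; right boundaries are mirrored so offsets
  x > 0 always point into the region and x < 0 outside, with x = 0 at
  the boundary. Signals binned at the metaplot width directly (or at a
  divisor of it, then averaged down). When the flanks of nearby
  regions overlap, bins are still aggregated — there is no natural
  exclusion rule — but `exclude_overlapping = TRUE` skips boundaries
  whose flank window touches another region. Size strata default to
  quartiles of region size (the conventional presentation); pass
  `size_strata = NULL` for a single stratum or explicit `(min, max)`
  pairs. Regions shorter than one bin are skipped with a warning.

# Flow cytometry

`detect_peaks()` histograms the *log* intensities with the exact
Freedman-Diaconis width, smooths the counts over 3 bins, takes the
`n_peaks` highest local maxima and refines each center with three
mean-shift passes (mean of events within ±15% of the current center).
Log space is the right coordinate system here: ploidy populations sit
at 2× spacings with approximately constant CV, so in log space the
peaks are equally spaced and equally wide, whereas a linear-space
bandwidth chosen from the whole mixture's IQR is dominated by the
2C-8C spread and can blur the closely spaced low-ploidy peaks
together. The ±15% refinement window sits safely inside the 2× spacing.

`peak_cv()` gates events in a symmetric multiplicative window around a
center (default ±25%, explicit rather than inherited from any
acquisition software, so CVs are comparable only within this package)
and returns `100·sd/mean` — exactly scale-invariant, demanding ≥ 50
gated events. `normalize_cv()` expresses a sample CV relative to wild
type and `cv_replicate_summary()` reports mean ± sd across replicates.

# The synthetic-data generator

`sim_config()` fixes the simulated study conditions; each
`simulate_*()` stage is deterministic given its seed (independent
streams derived from the base seed by fixed offsets, so stages are
reproducible in isolation).

* **Genome** (default 5 chromosomes × 1 Mb): two heterochromatin
  patches per chromosome, 20–100 kb, placed without overlap in the
  central 40% (pericentromeric) and snapped to the 100-bp bin grid; TEs
  tiled with exponential gaps to cover 60% of patch bp vs 10% outside
  (heterochromatin is TE-dense), lengths 0.5–8 kb, superfamilies drawn
  as 45% LTR/Gypsy, 20% LTR/Copia, 15% LINE/L1, 10% DNA/MuDR, 10%
  RC/Helitron — a Gypsy-dominated pericentromere as in *Arabidopsis*.
* **DNA reads**: per-100-bp-bin Poisson counts, mean 50 in wild type
  and κ × 50 inside patches for the mutant (default κ = 2); positions
  uniform within the bin, strands random. The copy gain is modeled as
  a uniform per-patch factor because the caller only sees aggregate
  coverage and observed gains track patch boundaries; κ has no
  measured value to inherit, so it is a configuration parameter. No
  fragment-length model (5'-position counting makes it irrelevant),
  no GC or mappability structure.
* **RNA-seq** (2 replicates per genotype, 5M reads/library): 30% of
  TEs are transcriptionally active with baseline RPKM ~
  lognormal(log 10, 0.8); the rest sit at RPKM 0.02, so roughly half
  of all TEs draw zero counts and exercise the zero-replacement rule.
  50 planted TEs get an 8-fold mutant mean. Counts are negative
  binomial — the standard overdispersed count model — with dispersion
  0.01, appropriate for replicates of pooled tissue from one inbred
  genotype; planted TEs are drawn from the *expressed* subset, since
  fold-change recovery is only a well-posed question for features with
  measurable baseline.
* **Methylome**: unique site positions at 0.03 sites/bp, contexts
  assigned at random, binomial counts at depth 20 with means CG/CHG/CHH
  = 0.8/0.4/0.1 in heterochromatin vs 0.1/0.03/0.01 outside — the
  canonical ordering and magnitudes for plant pericentromeres. No
  bisulfite conversion error or context calling from sequence.
* **FACS**: Gaussian mixture at 100/200/400/800 a.u. (2C–16C) with
  CVs 4/4/5/5% and weights 0.4/0.3/0.2/0.1, 10,000 events (the
  conventional minimum), true component labels retained.

What passing tests show — and what they do not: the generator matches
the *statistical* structure the callers assume (Poisson/NB counts,
binomial methylation, Gaussian peaks, patch-shaped gains). Real data
add mappability holes, copy-number polymorphism, partial re-replication
penetrance, bisulfite conversion bias and instrument drift; recovery on
simulation validates the implementation, not robustness to those.

# Validation scale and numerical choices

The test suite validates each operator against independent oracles
(exhaustive hypergeometric enumeration for Fisher, the step-up
definition for BH, all-rank-split enumeration for the rank-sum, brute
force interval scans for merging/overlap, direct convolution for
smoothing) and each caller against planted truth, at sizes chosen to
make every check sharp yet quick: a 5-Mb genome at 50 reads/100-bp bin
(~2.2M placements/sample) for region recovery, ~2,000 TEs with 50
planted for derepression recovery plus 20 null seeds, 10,000-event
mixtures for FACS. Degenerate inputs are defined, not crashed:
constant ratio tracks call nothing, zero-coverage methylation is
missing rather than 0, all-tied rank-sum input gives p = 1, and
all-zero expression samples are an error (the replacement floor is
undefined).

# Limitations

* The caller quantifies *where* coverage is elevated, not the copy
  number itself; duplicate saturation and library-size shifts compress
  the log2 scale (see above), so `mean_log2` is a signature, not an
  estimate of κ.
* Fisher's exact test on deep libraries is sensitive to tiny relative
  changes; the fold-change criterion, not the p-value, is the
  selective filter at depth.
* Metaplot flanks of nearby regions can overlap; aggregation does not
  exclude them by default.
* Peak CVs depend on the explicit gate; they are comparable within
  this package, not with values from acquisition software.
* No alignment, bisulfite mapping, FCS binary parsing, origin-level
  replication modeling, or ploidy deconvolution: the package consumes
  aligned placements, methylation calls, counts and exported event
  intensities.
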