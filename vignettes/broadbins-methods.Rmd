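---
title: "Methods: binned analysis of broad histone marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned analysis of broad histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Why bins

Broad histone modifications spread over domains of tens of kilobases to
megabases. Peak callers tuned for sharp binding sites fragment such domains
into intervals whose boundaries carry little meaning, and every downstream
comparison inherits those intervals. `broadbins` instead fixes a uniform
window grid (BED semantics, 0-based half-open, every window `bin_width`
base pairs except a possible chromosome-end remainder) and treats the
per-window read count as the elementary observation. All structure
downstream — scatterplots, clustering, differential binding, enrichment —
lives on this one shared grid, so nothing depends on a reference interval
set.

The choice of window size belongs to the user and should match the scale of
the expected biology: 1–10 kb for localized changes, ~100 kb for losses of
very broad domains. Counting reads into windows is upstream of this package
(any coverage counter works); the package starts from BED files with the
count in a configurable column (default column 4).

# Normalization

The default is plain library-size scaling to counts per million. This is a
deliberate, central design position rather than a simplification:
median-ratio and TMM factors assume that most features do not change
between samples. A knockout that removes a broad mark from a large part of
the genome violates that assumption, and composition factors then absorb
part of the genuine loss — shifting unchanged bins toward apparent gain
and shrinking the real depletion. Both factor methods are nevertheless
implemented (`median_ratio_factors`, `tmm_factors`) because they are
appropriate when changes are expected to be sparse, and because comparing
the two normalizations on simulated data is itself informative
(`benchmark_run` does exactly that). TMM uses the canonical trim fractions,
30% two-sided on M and 5% on A, with precision weights; factors are
rescaled to geometric mean 1, so only cross-sample ratios are meaningful.
A caveat the test suite documents: with strictly one-sided composition
outliers the rank-based trim window is asymmetric and any faithful TMM
(ours and edgeR's equally) retains a residual factor error of a few
percent.

Input correction offers a log2-ratio mode (default, pseudocount 0.5) and a
subtract-and-floor mode. The ratio is standard for ChIP versus input;
flooring the subtraction avoids negative coverage. Quantitative scaling
multiplies depth-normalized signal either by the mass-spectrometry
genome-wide modification percentage divided by 100, or by 10^6 over the
exogenous (spike-in) read count; the ChIP-Rx constant is arbitrary and
cancels in any two-sample comparison.

BigWig outputs are written in linear space; the log2 transform (default
pseudocount 1 on the counts-per-million scale) is applied downstream, and
every track records its space so a double log is impossible.

# Replicates and cohort structure

PCA and correlation clustering run on the log2 signal of bins surviving the
low-count filter. The low-count filter sums raw counts **across** samples
(default threshold 1): filtering per sample would preferentially discard
bins present in only one condition, which are exactly the differential
ones. PCA centers but does not scale by default, and each component's sign
is fixed so the largest-magnitude loading is positive, making coordinates
reproducible bit-for-bit. Replicate merging is a per-bin arithmetic mean in
the space of its inputs; since a mean of logs is not the log of a mean, the
default workflow merges linear tracks and logs afterwards.

# Genic/intergenic classification

The genic compartment is the union of all gene intervals (strand ignored;
overlapping or book-ended intervals merged); intergenic is the complement.
A bin is genic when at least half of its bases are genic — majority
overlap, with the boundary resolving to genic. The rule is configurable;
majority overlap is deterministic and symmetric for the 10 kb bins this
workflow typically uses.

# Clustering bins

Bins are clustered in the same two-dimensional space the scatterplot shows:
the (x, y) pair of log2 signal in the two compared samples, with no
standardization — the axes share units, and rescaling them would distort
the diagonal that separates loss from gain. The algorithm is HDBSCAN,
implemented in the package: core distance of each point as the distance to
its `min_samples`-th nearest neighbour (the point itself counts), mutual
reachability distance, a minimum spanning tree built by Prim's algorithm
with rows computed on the fly (O(n) memory), a single-linkage hierarchy,
condensation at `min_cluster_size`, and excess-of-mass cluster selection.
`min_samples` is the conservativeness dial: larger values inflate core
distances, push marginal points into noise and restrict clusters to denser
regions. Merges at distance zero (duplicate points) are handled by capping
the density level at 10^12.

Cluster labels must be stable to be usable downstream, so letters are
assigned by a fixed rule: descending size, ties by ascending centroid x
then y. Determinism notes: for a fixed input order results are exactly
reproducible; under input permutation the only possible changes come from
ties in mutual-reachability distances (points equidistant from two dense
regions), which is also true of reference implementations. More than 26
clusters is an error suggesting a larger `min_cluster_size` — in practice a
two-sample signal plane has a handful of density modes.

The runtime is quadratic in the number of points; the 50,000-bin scale of a
10 kb binning of selected regions is practical, while full-genome 1 kb
grids should be clustered on a subsample or a coarser grid.

# Differential binding

The per-bin statistic is `d = |m| / (a1 + a2 s)` with `m` the difference of
group means of log2 signal and `s` the pooled standard error. `(0, 1)`
recovers the ordinary absolute t statistic; `(1, 0)` the absolute mean
difference. The pair and a top-list size `k` are selected by maximizing the
reproducibility Z-score over a grid: for `B` bootstrap pairs (replicates
resampled with replacement within each group) the top-`k` overlap fraction
`R_k` is averaged, the same quantity `R0_k` is computed with group labels
permuted, and `Z = (R_k − R0_k)/sd(overlaps)`. Rankings with `a2 = 0` do
not depend on `a1`, and the implementation collapses those duplicates. Tie
break: smaller `a1`, then `a2 = 1`, then smaller `k`. Grids are
config-exposed; defaults are `a1 ∈ {0, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2,
3, 5}`, `a2 ∈ {0, 1}`, and a quasi-geometric `k` grid from 10 up to a
quarter of the bins. `B = 100` and `n_perm = 100` are the package defaults,
sized so that a 50,000-bin, 3 vs 3 analysis completes in well under a
minute; both can be raised for final analyses.

The FDR is permutational: for every distinct relabelling of the samples
into the original group sizes, null statistics are computed with the
selected `(a1, a2)`, and `FDR(g) = mean_p |{d_p ≥ d_g}| / |{d_obs ≥ d_g}|`.
Two numerical decisions matter here. First, the identity relabelling is
excluded from the null: its statistics are the observed ones, so including
it would put a hard floor of 1/(number of relabellings) under every FDR —
at 3 vs 3 (10 distinct splits) nothing could ever reach 0.05. Second, the
raw ratios are monotonized step-up (each bin takes the minimum over itself
and all weaker bins) and clipped to [0, 1], which makes the FDR
non-increasing in `d`, the property a threshold rule needs. When the
requested permutation count exceeds the number of distinct relabellings the
enumeration is exact; at 3 vs 3 that means 9 null splits, so FDR resolution
is coarse and small designs are intentionally conservative.

Two groups with at least two replicates each are required; the statistic is
undefined otherwise and the error says so. The exploratory parts of the
package (scatterplots, clustering, enrichment) work fine with single
replicates. Clustering is computed without reference to differential
status, so a bin's cluster letter and its FDR are independent annotations.

Randomness: one seed governs a run; bootstrap and permutation draws use
separate sub-streams (the permutation seed is offset by a constant), so
changing `B` does not silently change the FDR draws.

# Enrichment

A cluster is tested against each annotation region set with a two-sided
Fisher exact test on the 2×2 table of cluster/background versus
overlapping/not, where overlap is any shared base pair (the same rule as
blacklist removal). The background universe is either all surviving bins or
only the genic / only the intergenic ones: a predominantly intergenic
cluster tested against an all-bins background would appear "enriched" for
every intergenic-leaning annotation class, and stratification removes that
confounding. The reported odds ratio is the sample odds ratio `(ad)/(bc)`
with a Haldane–Anscombe 0.5 correction only when a zero cell exists; the
p-value always uses the uncorrected table. Benjamini–Hochberg adjustment is
applied across the sets tested in one call, and direction (enriched /
depleted) follows the odds ratio, so one call reports both tails.
Annotation databases are supplied by the user as BED files or directories
of them; none are bundled.

# The synthetic generator

`simulate_trackset` emulates the structure that matters to this workflow: a
uniform 10 kb grid on one synthetic chromosome; a genic fraction (default
0.5); covered bins carrying signal (default fraction 0.5, mean 200 reads
per bin) against low background (mean 5); negative-binomial counts with
dispersion 0.1 shared across replicates of both groups; and a planted
depletion applied to the altered group only, as a per-read binomial
thinning (keep probability `depletion_factor`, default 0.3) of a fraction
of the covered target-class bins. The default depletion fraction is 0.5 of
the covered intergenic bins, reflecting the regime this package targets —
a knockout removing a broad mark from roughly half of the signal-bearing
genome; `depletion_fraction = 1` expresses the full global-loss scenario.
Binomial thinning is the exact model of read downsampling, and
`downsample_regions` applies the same operation to any real track set.

What the generator does **not** emulate: spatial autocorrelation along the
chromosome (real broad-mark domains are contiguous; bins here are
exchangeable), mappability and GC structure, replicate-specific efficiency
differences, and input/background asymmetries. Tests passing on this
generator therefore certify the statistical machinery — normalization
arithmetic, ranking, FDR calibration, confusion accounting — not the
genome-specific robustness of any particular dataset.

Confusion counting defines true positives as truly depleted bins called
significant with negative logFC; significant calls on invariant bins in
either direction, and depleted bins called upregulated, are false
positives. Precision, specificity, sensitivity and F1 follow the usual
formulas, with zero-denominator metrics reported as `NA`.

# Problem sizes and expected behavior

The test suite runs the full pipeline on a 50,000-bin, 3 vs 3 fixture with
thinning to 30% in 20% of covered intergenic bins (about a minute), a
5,000-bin null-calibration run, and smaller parameterised fixtures per
module; `scripts/acceptance.R` recomputes the same quantities from scratch.
Two behaviors of the method under these conditions are worth stating
plainly. With the planted bins present in the permutation null, per-bin
FDRs are inflated near the detection boundary, so sensitivity saturates
below 1 even for strong effects — the cost of a null that makes no
distributional assumptions. And when the depleted compartment is small
(here ~5% of bins), TMM's trimmed mean excludes it entirely and TMM
normalization performs on par with library-size scaling; the advantage of
library-size-only normalization appears when the depleted share exceeds
the trim fraction, i.e. under genuine global loss (the
`depletion_fraction = 1`, high-coverage geometry), which is the scenario
the mechanism test in `test-simulate.R` exercises.

# Limitations

* Per-bin inference only; merging adjacent significant bins into regions is
  left to standard interval tools.
* Two-group designs; no covariates, batch terms, or multi-factor layouts.
* The permutation FDR needs replicates and is coarse for the smallest
  designs (2 vs 2 has three distinct relabellings, two usable).
* Clustering is quadratic in bin count.
* BAM processing, genome annotation bundles, and curated region databases
  are out of scope; the package consumes standard BED/GFF/bigWig files the
  user provides.
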