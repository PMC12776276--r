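---
title: "Topographic reconstruction of retinal gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic reconstruction of retinal gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotopo)
```

## The problem

Dissociated single-cell RNA-seq destroys spatial context. In the developing
retina, however, position along the dorso-ventral (DV) and naso-temporal
(NT) axes is encoded in the expression of well-characterized marker genes:
dorsal markers such as *Tbx5* and *Aldh1a1*, ventral markers such as *Vax1*
and *Aldh1a3*, nasal markers such as *FoxG1*, and temporal markers such as
*FoxD1*. retinotopo exploits this molecular coordinate system to place
every retinal progenitor cell back onto a virtual 2D flat mount, producing
per-gene topographic expression maps, detecting spatially patterned genes,
and comparing the reconstructions quantitatively with RNA-FISH images of
real flat mounts.

## Positional scores

Each cell receives four module scores (dorsal, ventral, nasal, temporal).
A module score is the mean log-normalized expression of the marker set
minus the mean of expression-matched control genes: all genes are ranked
by mean normalized expression and split into `n_bins` equal-frequency bins
(default 24, ties broken by gene order), and for each set gene `n_ctrl`
controls (default 100) are drawn from its bin — without replacement unless
the bin is smaller than `n_ctrl`. Control pools are drawn per set gene and
concatenated, duplicates allowed. The subtraction removes the cell-level
expression baseline that would otherwise dominate the score. The RNG seed
is a required, recorded parameter (default 0), and scores are bit-for-bit
reproducible given it.

The composite coordinates are

* `DV.Score = dorsal − ventral`
* `NT.Score = nasal − temporal`

Scores are computed on the full dataset rather than per library: the score
distributions change little between batches at this marker density, and a
single control pool keeps the composite scale comparable across all cells.

Normalization is the standard per-cell size normalization with a scale
factor of 10,000 followed by `log(1 + x)`. The scale factor is a
convention, not an inference; it is recorded in the dataset object.

## Spatial binning, smoothing, clipping

Scored cells are discretized on a regular `G x G` grid over
(NT.Score, DV.Score), with equal-width bins spanning the observed range of
each axis (half-open intervals, last bin closed). Species presets reflect
cell density in each compiled dataset:

| preset  | grid    | min cells/bin | min counts/bin | sigma | clip |
|---------|---------|---------------|----------------|-------|------|
| chicken | 51 x 51 | 3             | 20             | 1.0   | 94th |
| human   | 40 x 40 | 3             | 15             | 1.0   | 94th |
| mouse   | 51 x 51 | 5             | 30             | 1.0   | 94th |

"Counts per bin" is read as total raw transcript counts summed over the
bin's member cells — the least restrictive of the plausible readings and
the one that tracks sequencing support rather than any single gene. The
clip default of 94 is the midpoint of the stated 93rd–95th percentile
range; it can be overridden per species.

A gene's map holds the mean normalized expression of each valid bin.
Smoothing is mask-aware normalized convolution,
`K*(values·valid) / K*(valid)`, with an isotropic Gaussian kernel of SD
`sigma = 1` grid unit truncated at radius `ceiling(4*sigma)` (discrete
mass loss ~6e-6). Normalized convolution was chosen over
smooth-then-mask because it neither leaks zeros from empty bins into the
map nor shrinks boundary values; the smoothed layer is defined wherever
the convolved mask is positive, but all statistics are read on valid bins.
Percentile clipping caps the smoothed layer at the preset percentile of
its defined values (linear-interpolation percentile), taming sparse-bin
outliers.

## Spatially variable genes

Spatial structure is scored by Moran's I on the smoothed map over valid
bins, with binary queen (8-neighbor) contiguity weights; a rook option
exists mainly because the 2 x 2 checkerboard rook case has the exact value
−1 and anchors the implementation analytically. The weights are a design
choice — the statistic's source describes no lattice weights — and queen
contiguity is the standard choice for raster lattices.

Significance is by permutation (default `n_perm = 999`, seeded), one-sided
for positive autocorrelation, with two calibration safeguards that matter
in practice:

1. **Smoothing is re-applied to every permutation.** Smoothing induces
   strong lattice autocorrelation in pure noise; permuting smoothed values
   directly would declare every gene spatially variable.
2. **Variance-standardized residuals are permuted.** Bin means have
   variance proportional to `1/n_cells`, and cell density is itself
   spatially smooth, so raw bin values are not exchangeable under the
   null; permuting them is markedly conservative. The test permutes
   `sqrt(n_i) * (x_i − mean)`, which is exchangeable for a spatially flat
   gene, and uses I of the smoothed standardized field as the test
   statistic. The reported `I` remains Moran's I of the smoothed
   expression map.

On the 500 flat decoy genes of the benchmark bundle the raw rejection rate
at `p < 0.01` is at the nominal level (0.6–1.4% across seeds).

Genes are retained as spatially variable at BH `q < 0.01` (the global
threshold elsewhere in the package is `q < 0.05`). Note an intrinsic
resolution floor: with `n_perm = 999` the smallest attainable p-value is
1/1000, so with `m` tested genes and `k` true positives the best
attainable q is `m / (1000 k)`; on the benchmark (519 genes, 18 patterned)
that is ~0.029, and the strict `q < 0.01` filter can only fire with
`n_perm` of roughly 3,000 or more. Workflows that need the SVG set at
moderate permutation counts should either raise `n_perm` or use the
global `q < 0.05` threshold, as the demonstration pipeline does.

## Anchors and pattern groups

Anchor selection is a greedy scan over significant genes in decreasing
Moran's I (ties broken by input order): a gene becomes an anchor iff its
maximum cosine similarity to all anchors selected so far is below
`tau_redundancy` (default 0.9), stopping at `A_max` (default 20) anchors.
Every significant gene is then assigned to its most similar anchor. An
anchor forms a cluster if at least `min_members` genes besides itself are
assigned at similarity `>= tau_redundancy`, and cluster-forming anchors
that are each other's most similar anchor (mutual nearest neighbors) are
merged, transitively. The greedy-plus-redundancy reading and the
mutual-nearest-neighbor rule are declared reconstructions of a procedure
described only qualitatively by its source; both thresholds are
parameters so alternatives can be swapped in.

One practical caveat: cosine similarity is computed on the smoothed
expression fields, which are non-negative and share the baseline
expression floor of log-normalized data. When patterns ride on a large
common floor (e.g. genes whose off-state is within an order of magnitude
of their on-state), pairwise cosines are compressed toward 1 and gradient
markers can collapse onto few anchors at `tau = 0.9`. Sharply restricted
genes — the regime the anchor analysis targets — separate cleanly, as the
archetype recovery tests show.

## 1D profiles and clustering

Axis profiles bin cells along one composite score (default 50 bins,
matching the published profile resolution); bins covered by 50 cells or
fewer are flagged low-confidence rather than dropped. Profiles are
linearly interpolated onto a common axis spanning the union of ranges —
exact on nodes, never extrapolating — at a step that defaults to the
data's own resolution (the 8.12 um block pitch for FISH profiles, the bin
width for score-space profiles). Pairwise Pearson correlations use only
jointly observed positions (at least 3); missing correlations are imputed
as 0 before clustering, with a warning, to keep the matrix complete
without fabricating similarity. Clustering is average linkage on
`1 − r` distance, and the dendrogram is reordered by exact
dynamic-programming optimal leaf ordering, verified against exhaustive
search over all consistent orderings for up to 8 leaves. Cross-modal
comparison rescales each profile's positions and values to [0, 1] (the
modalities' units are incommensurate) and interpolates the denser profile
onto the sparser one's positions.

## Region differential expression

A region is the set of valid bins whose smoothed marker expression is at
or above the `q_region` quantile (default 0.95), or an explicit bin list —
the automated counterpart of manually circling a marker-enriched
territory. Cells are pseudobulked by embryo and in/out membership;
pseudobulks with 100 cells or fewer are excluded. Each gene is tested
with a negative-binomial GLM: log link, design `~ group`, offset
`log(total pseudobulk counts)`, per-gene ML dispersion, Wald test on the
group coefficient, BH correction, and significance at `|log2FC| > 1` with
`q < 0.05`. There is no dispersion shrinkage across genes — a declared
simplification relative to shrinkage-based tools. Wald p-values with
per-gene ML dispersion are known to be somewhat liberal at 6 + 6
pseudobulks (raw rejection ~10% at nominal 5% on simulated nulls); the
BH-adjusted decisions remain conservative (0–0.1% q < 0.05 rejections on
a 2,000-gene null), and an 8-fold spiked gene is recovered with the
correct sign in 20/20 seeded replicates. Genes whose NB fit fails to
converge fall back to a Poisson GLM and are flagged in the result table.

## FISH quantification

Flat-mount images (oriented nasal-right, ventral-bottom; 0.3248 um/px)
are quantified per 25 x 25-pixel block as the mean intensity over
foreground (mask) pixels only; edge blocks are partial, and masked-out
pixels are excluded rather than zero-filled so edge blocks are not biased
downward. Block maps are min-max normalized to [0, 1], optionally
column-/row-normalized to emphasize DV or NT gradients, and profiled
along 500 um-wide strips (1539 px at default pixel size) anchored at a
user-set origin, typically the high-acuity area. Strip positions where
fewer than 80% of blocks are defined are dropped as background-dominated
edges. Strip statistics are computed over blocks, not raw pixels,
consistent with profiling the binned matrices. Origin-aligned profiles
from multiple flat mounts are linearly interpolated to a common axis and
averaged with per-position sample counts and SEM/SD. The FIJI-style
pre-filters (outlier removal, Gaussian blur, background subtraction) are
available but off by default: quantification operates on raw images.

## The synthetic benchmark

All validation runs on synthetic data with known ground truth, generated
by `make_benchmark_suite()`:

* 20,000 cells with latent positions uniform on the unit disk
  (`u` = NT, `v` = DV), 10 embryos round-robin;
* every shipped axis marker follows its axis gradient archetype; two
  held-out genes carry localized patterns — `FGF8SIM`, a nasal-central
  spot at (0.35, 0) with width 0.25, and `CYP1B1SIM`, an oblique stripe —
  mirroring the canonical spot-and-stripe geometry of the genes they are
  named after; 500 flat decoys provide the null set;
* counts are negative binomial, `variance = mu + phi mu^2` with
  `phi = 0.3`, gene mean
  `mu = baseline (1 + amplitude * P(u, v)) * size_factor`, baseline 2
  counts, lognormal size factors (sdlog 0.35);
* `amplitude = 9` (10-fold peak-to-trough). This is deliberately
  conservative: the axis markers being emulated are near on/off domain
  genes whose effective fold changes in situ are far larger;
* a single high-abundance flat `BACKGROUND` component (x7000 baseline,
  near-Poisson dispersion 5e-4) stands in for the unpatterned remainder
  of the transcriptome. Without it, the patterned markers would be ~10%
  of each cell's library, per-cell totals would track position, and
  "flat" decoys would be genuinely spatially patterned after size
  normalization; conversely, a single overdispersed background gene
  would inject unrealistic total-count noise into every normalized
  value. Real libraries spread this mass over ~15,000 genes, which is
  what the aggregate emulates.

Matched FISH images render the same archetypes on a disk mask with
additive Gaussian noise, so the two modalities share one generative
truth. When a reconstruction is scored against "noiseless truth", the
reference is the archetype passed through the same measurement transform
— the expected log-normalized expression `expected_norm_expression()` —
because maps estimate expression (which carries every gene's baseline),
not the bare [0, 1] pattern. Spot localization is read as the centroid of
the percentile-clip plateau over valid bins: the argmax of an unclipped
noisy field is unstable (a 4-cell rim bin can beat the true plateau), and
the clip is the pipeline's own outlier-handling mechanism.

What the generator does **not** emulate: batch and library chemistry
effects, doublets and ambient RNA (the pipeline consumes QC'd matrices by
contract), realistic gene-gene correlation beyond shared position,
mapping nonlinearity between score and anatomical position, and the real
datasets' gene counts and depth distributions. Passing tests therefore
demonstrate correctness of the machinery and calibration of its
statistics under the stated model, not performance on any real library.

## Problem sizes and numerical choices

The test and validation suites use the 20,000-cell benchmark for recovery
and calibration checks, 6 x 6 lattices for the Moran brute-force oracle,
2,000-gene nulls and 20 replicate spikes for the DE checks, and up to
8-leaf trees for the exhaustive leaf-ordering oracle — sizes at which
every oracle is exact or its Monte-Carlo error is negligible, and the
whole suite runs in minutes on one CPU. Other numerical conventions:
percentiles and quantiles use the linear-interpolation definition (R type
7); bin intervals are half-open with the last bin closed; gene symbols
match case-insensitively with original casing preserved; Moran's I on a
constant field is an error, not silently 0; anchor ties in Moran's I
break by input order; volcano ties break by q, then |log2FC|, then
symbol. Seeds are explicit arguments everywhere randomness exists, and
every pipeline artifact records its parameters and a configuration hash.

## Known limitations

* Axis scores are ordinal, not metric: grid position is a monotone but
  nonlinear image of anatomical position, so distances on the grid are
  not micrometers.
* The SVG permutation test conditions on the observed binning; it does
  not propagate score uncertainty.
* The NB Wald test is liberal at raw-p level for few pseudobulks (see
  above); decisions should be made on q-values, as the package does.
* Orthology mapping is offline table lookup only; no live database
  queries are made anywhere in the package.
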