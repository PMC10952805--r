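---
title: "imcpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{imcpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and conventions behind each stage of
the package, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the field's practice is genuinely open.

# Data model

The central container is the `CellTable`, a `SingleCellExperiment` with
channels as rows and cells as columns. The `"raw"` assay holds per-cell
mean intensities; the pipeline adds `"compensated"`, `"transformed"`
(arcsinh), `"normalized"` (Z-score) and, for the comparison arm,
`"scaled01"` assays, so every processing level stays inspectable side by
side. Per-cell geometry and metadata (ROI, batch, within-ROI cell id,
centroids, area, edge flag, cluster assignments) live in `colData`;
channel metadata (metal, marker, clustering and blank flags) in `rowData`.

Coordinate convention, stated explicitly because image formats disagree:
pixel coordinates are 0-based with origin at the top-left, x = column,
y = row. At IMC resolution 1 pixel = 1 µm (the `pixel_size_um` slot of
`ChannelStack` generalizes this), so pixel counts are areas in µm² and
pixel distances are µm.

# Feature extraction

`extractFeatures()` computes, per labelled cell: the arithmetic mean of
each channel over the cell's pixels, area = pixel count × pixel size²,
the unweighted pixel centroid, and an edge flag set when any pixel lies on
the image border. Mean intensity (not sum) is used so cell size and
abundance stay separable.

**Hot-pixel capping.** IMC detectors produce rare isolated "hot" pixels
that can dominate a small cell's mean. `capHotPixels()` clips each
channel to its [low, high] percentiles computed over all pixels of the
ROI, before measurement. The package default is (0, 99.9) — capping only
the extreme upper tail — because clipping 5% of pixels at both ends is
aggressive enough to flatten genuinely bright structures; the (5, 95)
configuration used in some IMC workflows is one argument away and
documented in `?capHotPixels`. Capping precedes feature extraction
(whether to cap before or after measurement is not standardized; before is
the conservative choice since it also protects the centroid-weighted
statistics users may add downstream).

**Percentile convention.** Every percentile in the package — capping,
rSD, 0–1 scaling — uses linear interpolation between order statistics
(R's `quantile(type = 7)`). This matters: rSD and hence Rd values are not
comparable across software that interpolates differently. One subtle
consequence, asserted in the tests: re-capping a capped image at the same
percentiles is *not* bit-identical, because the percentiles of the
clipped distribution shift slightly within the clipped range; clipping at
fixed bounds is idempotent, clipping at re-estimated bounds only nearly
so.

**Spillover compensation.** Cell-level mean intensities m are modelled as
m = c S with S the spillover matrix (rows = source channel, columns =
receiving channel, unit diagonal, off-diagonal in [0, 1)). The default
solver is nonnegative least squares (`pracma::lsqnonneg`), matching CyTOF
compensation practice and guaranteeing c ≥ 0; a plain matrix inverse with
zero-clipping is available for speed. Compensation operates on cell means
rather than pixels — mixing is linear, so it commutes with averaging; the
mask-level simulation verifies the inversion end to end to 1e-6.
Spillover matrix *estimation* from single-stain controls is out of scope;
the matrix is consumed, not produced.

# Transformation and normalization

**Arcsinh and the Fisher discrimination ratio.** Variance in cytometry
data grows with signal, so distances at high intensity mean less than the
same distances at low intensity; `asinh(x / c)` stabilizes this. The
cofactor c is selected empirically by `titrateCofactor()`: for a gated
negative and positive population the Fisher discrimination ratio

$$ R_d = \frac{(\mathrm{median}_{pos} - \mathrm{median}_{neg})^2}
{\mathrm{rSD}_{pos}^2 + \mathrm{rSD}_{neg}^2},
\qquad \mathrm{rSD} = \frac{P_{84.13} - P_{15.87}}{2} $$

is evaluated on the transformed values across a cofactor grid, and the
maximizer wins. rSD is defined by percentiles (the half-width that equals
σ exactly for a gaussian) rather than the sample SD because cytometry
intensity distributions are heavy-tailed; Rd is invariant under a common
affine rescaling of both groups and converges to the raw-space ratio as
c → ∞. The default grid {150, 120, 100, 50, 20, 10, 5, 2, 1, 0.5, 0.1}
spans fluorescence-style values down to sub-unit compression. Ties in the
argmax break toward the smaller cofactor (stronger compression). Positive
and negative populations are supplied by gates or truth labels — no
automatic gating is attempted. On the package's bimodal generator
(exponential negatives at mean 0.3, lognormal positives at median 8) the
optimum among {100, 1, 0.1} is 1, the value recommended for IMC.

**Z-score scope.** `zscoreNormalize()` centers and scales each channel to
unit SD *within groups*. The default scope is per batch: a single global
Z-score is one affine map per channel and cannot change between-batch
structure, so only a per-group fit can remove batch effects; per-image
(`"image"`) and `"global"` scopes are offered for comparison. Constant
channels map to 0 with σ recorded as 0. A regime caveat, visible in the
simulations: a multiplicative batch gain becomes an additive shift after
arcsinh only where the signal is well above the cofactor (the log regime),
so per-batch Z-scoring aligns batch distributions essentially exactly for
positive markers at IMC scale but leaves residual shape differences for
channels whose signal sits in the linear regime near zero. The package's
batch-effect checks therefore use positive markers at the generator's
IMC-like scale.

**The 0–1 scaling arm.** `minmaxScale()` implements percentile-anchored
min-max compression per channel, globally. It is retained deliberately as
the negative control: being a global affine map per channel it cannot
remove batch structure, and the tests assert that it fails the
cross-batch alignment that per-batch Z-scoring achieves.

**Batch mixing entropy.** To turn "the batches overlap in the embedding"
into a number, `batchMixingEntropy()` computes, per cell, the Shannon
entropy of batch labels among its k = 30 Euclidean nearest neighbors,
normalized by log(#batches), averaged over cells — 1 when batches are
perfectly interleaved, 0 when separated. It is the quantitative stand-in
for the colored-UMAP inspection commonly used for this purpose.

**Double-positive screen.** `quadrantFractions()` gates two channels at
thresholds (≥ counts positive) and returns the four quadrant fractions.
The double-positive fraction of mutually exclusive lineage markers (CD3
vs CD79a) is a quick segmentation-quality screen — real cells cannot
co-express both, so DP events are segmentation chimeras. It is, however,
an insensitive screen; cluster-level fidelity (below) is the one that
actually separates segmentation qualities.

# Clustering

`trainSOM()` is an online self-organizing map on a rectangular grid
(default 10×10 = 100 nodes, the conventional first-stage granularity for
cytometry), with a gaussian neighborhood kernel and linearly decaying
learning rate (0.05 → 0.01) and radius (max(grid)/2 → 0.5) over
10 epochs. The codebook is initialized from randomly sampled data rows
and the presentation order is reshuffled each epoch; both draws come from
R's RNG under the required seed, so training is bit-reproducible. The
widely used cytometry implementations do not publish their exact internal
schedules, so these defaults are this package's own documented choice.
Final assignments are to the nearest codebook vector; the mean distance
to it is reported as the quantization error.

`consensusMetacluster()` merges the 100 nodes to (default) 30 consensus
clusters by agglomerative hierarchical clustering of the codebook vectors
— Euclidean distance, average linkage, configurable — cut at `n_meta`.
Plain hierarchical clustering was chosen over resampling-based consensus:
it is deterministic, transparent, and directly expresses "merge by
codebook similarity". `mergeClusters()` then applies the expert's manual
merge table (every consensus id must be covered; the error lists missing
ids), mirroring the annotate-and-merge step that typically reduces ~30
consensus clusters to ~20 biologically named types.

Cluster fidelity against a known truth is scored by the adjusted Rand
index (`clusterRecoveryScore()`). The package's segmentation-quality
analogue, exercised in the acceptance tests: on a clean 6-archetype
simulation SOM + consensus recovers the types (ARI ≥ 0.8), and averaging
20% of cells pairwise into doublet signatures — the feature-space effect
of under-segmentation — strictly lowers the ARI.

**Heatmap normalization.** `clusterMarkerHeatmap()` reports per-cluster
channel medians; `normalize = "column"` min-max rescales each cluster's
column to [0, 1]. Column-wise normalization is the display convention
that makes each cluster's defining markers legible regardless of overall
staining intensity; since "normalized by column" admits several formulas,
min-max was adopted and row-wise normalization is offered as well.

# Spatial neighborhood analysis

**Neighbor detection.** Two pixel-expansion geometries around each cell:

* `disc` — neighbors are all labels whose pixels intersect the
  morphological dilation of the cell's pixel set by the discrete
  Euclidean disc {(dx, dy) : dx² + dy² ≤ d²}; equivalently, labels with
  any pixel-centre within distance d of the cell. Symmetric by
  construction, and shape-aware.
* `bbox` — all labels with pixels inside the cell's bounding box expanded
  by d on each side (the classic implementation). It samples a
  shape-blind rectangle, so elongated or diagonal cells acquire neighbors
  well beyond d, it need not be symmetric, and its median neighbor count
  exceeds the disc's at every d — the package's tests assert the per-cell
  subset relation and the median-NN ordering on random tessellations.

The default distance is 5 px (= 5 µm), at which the disc method yields a
median of ~6–8 immediate neighbors in densely packed simulated tissue —
the physically sensible count for touching cells — while bounding boxes
overcount. Neighbor sets grow monotonically with d.

**Cell filtering.** Before testing, cells outside [20, 200] µm²
(inclusive) are dropped — sub-20 µm² objects are fragments, super-200 µm²
objects merged cells — as are cells touching the image border (partial
cells with distorted areas and truncated neighborhoods). Neighbor
detection runs on the full mask first; filtered cells are then removed
both as centers and as neighbors, so filtering can never create an
adjacency through a removed cell.

**Permutation test.** For an ordered pair (A, B) the statistic is the
mean number of B neighbors per A cell. The null shuffles cluster labels
uniformly over the image's filtered cells — preserving the per-image
composition, which is exactly what "cell identities mapped at random onto
the masks" means — 100 times, seeded. A pair is called +1 when the
observed statistic strictly exceeds more than (1 − α)·n_perm of the null
draws (α = 0.10), −1 symmetrically below, 0 otherwise. Strict inequality
is the conservative tie rule: a permutation-invariant statistic (e.g. a
single cluster) produces observed = null in every draw and lands exactly
on 0. Per-direction false-flag rates under random labels stay within
α plus three binomial standard errors in the package's 20-image
simulation.

**Occupancy and aggregation.** Clusters must be present in strictly more
than `occupancy_threshold` (default 0.01) of the images to enter the
analysis. The threshold is interpreted as a fraction of images — the
parameter's description in circulating implementations mixes percent and
fraction readings, so the package states its reading explicitly and flags
that aggressive occupancy filtering risks silently removing a defining
cluster of one sample group. Per-image ternary calls are averaged over
the images where the pair is defined, giving the [−1, 1] proportion
heatmap: +1 means every image called the interaction, −1 every image the
avoidance. Pairs defined in no image are NA rather than 0.

# The synthetic-tissue generator

The generator exists so that every stage above can be tested against
known truth. `generateLabelMask()` tessellates the image by Euclidean
nearest-seed growth from uniformly placed seeds (a planar Voronoi
partition, computed exactly by a small compiled kernel) and then carves a
1 px background rim between touching regions: at each 4-adjacent pair of
different labels the pixel on the higher-label side becomes background,
and wider gaps grow symmetrically from there. The rim reproduces the
background gutters real segmentation masks have between packed cells and
is the main knob controlling neighbor counts at a given pixel expansion.
With the default 500×500 px, 4500 seeds and 1 px rim, the achieved mean
cell area lands near the 45 µm² target (the calibration test asserts
[38, 52]). Cell types are drawn region-wise: follicle-like circles carry
their own composition against a background composition, giving the
spatially structured enrichment that drives the interaction/avoidance
benchmarks.

`renderChannels()` paints intensities from a cluster × channel archetype
matrix with per-cell-per-channel lognormal dispersion (reproducing the
right skew of positive marker distributions), multiplies by per-channel
batch gains (the batch-effect model), adds flat background, optionally
Poisson pixel noise, and mixes channels through a spillover matrix. The
truth table records pre-gain, pre-spillover cell means, so the forward
model is invertible: noiseless rendering recovers the archetypes exactly
through `extractFeatures()`, and spillover rendering is recovered by
`compensate()` to 1e-6.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: nucleus/membrane substructure and intensity
gradients within cells; z-plane signal mixing from the ablation depth;
actual segmentation errors (masks are perfect by construction — doublet
corruption is injected in feature space instead); spatial intensity
artifacts (stripes, ablation dropouts); and cell shapes beyond convex-ish
Voronoi polygons. Conclusions about segmentation robustness therefore
come from the controlled corruptions, not from the generator per se.

`generateBimodalChannel()` draws the negative population
Exponential(mean 0.3) and the positive LogNormal(median 8, log-sd 0.5) —
a gated marker channel at IMC scale with known membership, feeding the
cofactor titration.

# Reproducibility, sizes, and I/O

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; pipelines rerun byte-identically. The test suite and the
acceptance script size their simulations to run comfortably on one CPU:
titration at 5000 + 5000 cells; interaction/avoidance at 10 images of
256×256 px with ~1200 cells each; type-I control at 20 images of
120×120 px; tessellation calibration once at the full 500×500/4500
default; SOM benchmarks at 1200 cells × 6 channels. These sizes are the
package's chosen study conditions — large enough that the stochastic
checks are stable across seeds.

FCS export writes FCS 3.1, list mode, little-endian float32 for all
parameters — the simplest dialect that downstream cytometry software
reads. FCS parameters are numeric, so string metadata (ROI, batch, final
cluster) is written as integer codes with a sidecar `<file>.key.csv`
mapping codes back to names; the batch code thereby becomes a plottable
parameter. Blank panel channels are excluded from FCS output by default.
Label masks are relabelled to contiguous 1..n on ingestion with the
original ids retained in the `mapping` slot. A minimal FCS reader is
included for round-trip verification (values reproduce to float32
rounding).

# Known limitations

* Compensation assumes the linear mixing model with a known, well-
  conditioned spillover matrix; estimation from controls is out of scope.
* The Rd titration needs gated or truth-labelled negative/positive
  populations; no automatic gating is provided.
* Per-batch Z-scoring assumes each batch samples the same underlying
  biology; it will erase genuine global composition differences between
  batches, and its alignment is exact only in the arcsinh log regime (see
  above).
* The permutation test conditions on the observed mask and per-image
  composition; it detects label arrangement, not density effects.
* Bounding-box adjacency is intentionally kept non-symmetrized to mirror
  the classic implementation being compared against.
* Dimensionality-reduction methods (UMAP/tSNE/PacMap) and
  graph-community clustering are not re-implemented; users can embed the
  exported matrices with any external tool and score the result with
  `clusterRecoveryScore()`.
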