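# imcpipe

Optimized single-cell and spatial analysis of imaging mass cytometry (IMC)
data.

IMC rasters metal-antibody-stained tissue with a 1 µm laser and reads the
ablated material by CyTOF, giving ~40-plex images at 1 µm/pixel. After an
upstream segmentation step (Ilastik/CellProfiler/CellPose — out of scope
here), every downstream choice still matters: how per-cell intensities are
extracted and compensated, which arcsinh cofactor is used, how batch
effects are removed, how cells are clustered into types, and how spatial
neighborhood statistics are computed. `imcpipe` implements this
post-segmentation pipeline for R users (imaging/cytometry core facilities,
computational biologists), with an empirical metric for each choice and a
synthetic-tissue simulator so every stage can be validated against known
ground truth.

## What it computes

**Signal resolution (arcsinh cofactor).** Intensities are transformed by
`y = asinh(x / c)`. The cofactor `c` is chosen to maximize the Fisher
discrimination ratio between a gated negative and positive population:

    Rd = (median_pos − median_neg)² / (rSD_pos² + rSD_neg²),
    rSD = (P84.13 − P15.87) / 2

with linear-interpolation percentiles. On IMC-scale data the optimum is
`c = 1` — far below the 100–150 used in fluorescence cytometry and the 5
conventional for suspension mass cytometry.

**Batch normalization.** Per-batch Z-scoring of the transformed
intensities (`(y − μ_batch)/σ_batch` per channel) removes multiplicative
staining/acquisition batch effects that no single global affine map can
touch; `batchMixingEntropy()` quantifies the result (1 = batches perfectly
interleaved among each cell's nearest neighbors). 0–1 min-max scaling is
provided as the comparison arm that does *not* remove batch structure.

**Clustering.** A 10×10 self-organizing map (100 nodes) partitions cells;
the nodes are merged to 30 consensus clusters by hierarchical clustering
of the codebook (average linkage), then manually merged to named cell
types. `clusterRecoveryScore()` (adjusted Rand index) benchmarks cluster
fidelity against known truth — the most sensitive read-out of segmentation
quality.

**Spatial neighborhoods.** Neighbors are detected by morphological disc
expansion of each cell's pixel set (radius 5 px by default; the classic
expanded-bounding-box method is included for comparison and systematically
overcounts — median NN ~11 vs ~8 at 5 px in dense tissue). For every
ordered cluster pair, the mean neighbor count is compared against 100
random relabelings of the image; a pair is called interacting (+1) or
avoiding (−1) when the observed statistic beats more than 90% of the
permutations, and the per-image calls are averaged into a [−1, 1] heatmap
across images. Cells outside 20–200 µm² and cells touching the image
border are excluded first.

**Simulation.** `tissueSpec()`/`generateLabelMask()` build densely packed
Voronoi tissue with 1 px gutters, follicle-like regions and per-region
cell-type compositions; `renderChannels()` paints archetype intensities
with lognormal cell-to-cell dispersion, batch gains, spillover and
optional Poisson noise. Every generator is a pure function of its seed.

## Worked example

```r
library(imcpipe)

## 1. cofactor titration on a simulated marker channel (5000 negative,
##    5000 positive cells at IMC-like scale)
bm  <- generateBimodalChannel(n_neg = 5000, n_pos = 5000, seed = 42)
neg <- bm$value[bm$population == "neg"]
pos <- bm$value[bm$population == "pos"]
curve <- titrateCofactor(neg, pos, grid = c(100, 1, 0.1))
setNames(round(curve@rd_values, 2), curve@cofactors)
#>   100     1   0.1
#>  3.45 21.27 11.01
rdOptimum(curve)
#> [1] 1

## 2. spatial neighborhood analysis on a simulated follicle image where
##    clusters A and B are interleaved inside a follicle and C fills the rest
sc  <- simulateInteractionScene("interaction", seed = 3)
adj <- findNeighbors(sc$mask, neighborConfig(distance_px = 5))
medianNN(adj)
#> [1] 8
res <- spatialInteractionAnalysis(
  list(roi1 = syntheticCellTable(sc, roi_id = "roi1")),
  list(sc$mask), neighborConfig(seed = 5))
interactionAggregate(res)
#>       neighbor
#> center  A  B  C
#>      A  1  1 -1
#>      B  1  1 -1
#>      C -1 -1  1
```

Reading of the numbers: the cofactor 1 transform separates the negative
and positive populations six times better (Rd 21.3 vs 3.4) than the
fluorescence-style cofactor 100; a 5 px disc expansion finds a median of 8
immediate neighbors in densely packed tissue; and the follicular A/B pair
is called a significant interaction (+1) while both avoid the surrounding
filler cells (−1) — exactly the built-in spatial structure.

The full chain (features → transform → cluster → spatial → FCS/CSV export)
runs from one YAML config via `runPipeline()`, or from the shell through
the thin wrapper `inst/scripts/optimal.R run --config run.yaml`.

## Documentation

The methods vignette (`vignettes/imcpipe-methods.Rmd`) describes the
models, parameter defaults, numerical conventions and the simulator's
scope in detail; every exported function carries roxygen documentation.
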