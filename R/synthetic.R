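#' @include AllClasses.R utils.R io.R
NULL

#' Specification of a synthetic tissue geometry
#'
#' Describes a densely packed tissue to simulate: image size, target cell
#' count and mean area, the background rim between touching cells, and the
#' spatial composition — circular follicle-like regions with their own
#' cell-type mixture against a background mixture. Defaults emulate a
#' 500 x 500 um IMC ROI of lymphoid tissue at 1 um/pixel: ~4500 cells of
#' ~45 um^2 separated by 1-px segmentation gutters.
#'
#' @param width,height Image size in pixels.
#' @param n_cells Number of seed cells.
#' @param mean_area_um2 Target mean cell area (used for the feasibility
#'   check; the achieved mean emerges from the tessellation).
#' @param packing_gap_px Width of the background rim carved between
#'   adjacent cells (default 1; the knob controlling neighbor counts at a
#'   given pixel expansion).
#' @param follicles List of \code{list(center = c(x, y), radius,
#'   composition = named probabilities)} circular regions (0-based pixel
#'   coordinates).
#' @param background_composition Named cluster probabilities outside all
#'   follicles.
#' @param seed Integer seed; every generated quantity is a pure function
#'   of it.
#' @return A validated list of class \code{"TissueSpec"}.
#' @export
tissueSpec <- function(width = 500, height = 500, n_cells = 4500,
                       mean_area_um2 = 45, packing_gap_px = 1,
                       follicles = list(),
                       background_composition = c(stroma = 1),
                       seed = 1) {
  check_comp <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop(what, " composition must be a named probability vector")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " composition probabilities must be non-negative and sum to 1")
  }
  check_comp(background_composition, "background")
  for (f in follicles) {
    stopifnot(length(f$center) == 2L, f$radius > 0)
    check_comp(f$composition, "follicle")
  }
  if (n_cells < 1L) stop("n_cells must be positive")
  if (n_cells * mean_area_um2 > 0.95 * width * height)
    stop("infeasible density: n_cells * mean_area exceeds 95% of the image")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 mean_area_um2 = mean_area_um2,
                 packing_gap_px = as.integer(packing_gap_px),
                 follicles = follicles,
                 background_composition = background_composition,
                 seed = seed),
            class = "TissueSpec")
}

# Carve a background rim between adjacent Voronoi regions. First pass: at
# every 4-adjacent pair of different labels, the pixel on the higher-label
# side is set to background (a 1-px gutter per contact; which side loses is
# random because seed order is random). Further passes widen the gutter
# symmetrically by removing pixels 4-adjacent to background.
.carve_gaps <- function(lab, gap) {
  if (gap < 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  drop <- matrix(FALSE, H, W)
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift(lab, s[1], s[2])
    drop <- drop | (lab > 0L & nb > 0L & nb < lab)
  }
  lab[drop] <- 0L
  if (gap > 1L) for (g in seq_len(gap - 1L)) {
    bg <- lab == 0L
    drop <- matrix(FALSE, H, W)
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      drop <- drop | (lab > 0L & shift(1L * bg, s[1], s[2]) > 0L)
    lab[drop] <- 0L
  }
  lab
}

#' Generate a synthetic label mask with known cell types
#'
#' Space-filling tessellation by Euclidean nearest-seed region growth from
#' uniformly placed seed points, followed by carving a
#' \code{packing_gap_px}-wide background rim between touching regions —
#' reproducing the background gutters real segmentation masks have between
#' densely packed cells. Cell-type truth labels are drawn region-wise from
#' the follicle or background composition containing each cell's centroid.
#' Deterministic given \code{spec$seed}.
#'
#' @param spec A [tissueSpec()].
#' @return A list with \code{mask} (\linkS4class{LabelMask}),
#'   \code{clusters} (character truth label per cell) and \code{cells}
#'   (DataFrame skeleton: cell_id, centroid_x/y, area_um2, edge_flag,
#'   true_cluster).
#' @export
generateLabelMask <- function(spec) {
  stopifnot(inherits(spec, "TissueSpec"))
  H <- spec$height; W <- spec$width
  .with_seed(spec$seed, {
    pix <- sample.int(H * W, spec$n_cells)
    sr <- (pix - 1L) %% H + 1L
    sc <- (pix - 1L) %/% H + 1L
    lab <- .nearest_seed_cpp(H, W, sr, sc)
    lab <- .carve_gaps(lab, spec$packing_gap_px)
    mask <- .as_label_mask(lab)
    n <- mask@n_cells
    idx <- which(mask@labels > 0L)
    l <- mask@labels[idx]
    counts <- tabulate(l, nbins = n)
    row0 <- (idx - 1L) %% H
    col0 <- (idx - 1L) %/% H
    cx <- unname(rowsum(as.numeric(col0), l)[, 1] / counts)
    cy <- unname(rowsum(as.numeric(row0), l)[, 1] / counts)
    on_edge <- row0 == 0L | row0 == H - 1L | col0 == 0L | col0 == W - 1L
    edge <- unname(rowsum(as.numeric(on_edge), l)[, 1] > 0)

    clusters <- character(n)
    for (i in seq_len(n)) {
      comp <- spec$background_composition
      for (f in spec$follicles) {
        if ((cx[i] - f$center[1])^2 + (cy[i] - f$center[2])^2 <= f$radius^2) {
          comp <- f$composition
          break
        }
      }
      clusters[i] <- sample(names(comp), 1L, prob = comp)
    }
    cells <- DataFrame(cell_id = seq_len(n), centroid_x = cx, centroid_y = cy,
                       area_um2 = as.numeric(counts), edge_flag = edge,
                       true_cluster = clusters)
    list(mask = mask, clusters = clusters, cells = cells)
  })
}

#' Specification of synthetic marker intensities
#'
#' Describes how marker intensities are painted onto a generated mask: a
#' cluster x channel archetype matrix of raw mean intensities, cell-level
#' lognormal dispersion (reproducing the right-skew of positive marker
#' distributions), additive background, per-channel multiplicative batch
#' gains, an optional spillover matrix to mix channels with, and optional
#' per-pixel Poisson counting noise.
#'
#' @param archetypes Cluster x channel numeric matrix (dimnames required),
#'   entries >= 0.
#' @param sigma Log-sd of the per-cell lognormal multiplier (0 = none).
#' @param background Additive background level per pixel.
#' @param gains Multiplicative gain: scalar or named per-channel vector
#'   (all > 0); models the batch effect.
#' @param spillover Optional K x K spillover matrix over the channels.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param seed Integer seed.
#' @return A validated list of class \code{"IntensitySpec"}.
#' @export
intensitySpec <- function(archetypes, sigma = 0, background = 0, gains = 1,
                          spillover = NULL, noise = c("none", "poisson"),
                          seed = 1) {
  noise <- match.arg(noise)
  archetypes <- as.matrix(archetypes)
  if (is.null(rownames(archetypes)) || is.null(colnames(archetypes)))
    stop("archetypes must have cluster rownames and channel colnames")
  if (any(archetypes < 0)) stop("archetype intensities must be >= 0")
  if (any(gains <= 0)) stop("gains must be positive")
  if (!is.null(spillover)) .check_spillover(spillover)
  structure(list(archetypes = archetypes, sigma = sigma,
                 background = background, gains = gains,
                 spillover = spillover, noise = noise, seed = seed),
            class = "IntensitySpec")
}

#' Render marker channels onto a synthetic mask
#'
#' Per cell and channel the true mean intensity is archetype x lognormal
#' multiplier; the measured image further applies the batch gain, paints
#' the cell mean onto its pixels plus background, adds Poisson noise if
#' configured, and mixes channels through the spillover matrix. The
#' returned truth table records the pre-gain, pre-spillover cell means, so
#' the full measurement model can be inverted and checked.
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param clusters Truth cluster per cell (must match the archetype rows).
#' @param spec An [intensitySpec()].
#' @param roi_id,batch_id Identifiers for the generated image.
#' @return A list with \code{stack} (\linkS4class{ChannelStack}) and
#'   \code{truth} (\linkS4class{CellTable} whose \code{"raw"} assay holds
#'   the true cell means).
#' @export
renderChannels <- function(mask, clusters, spec, roi_id = "sim", batch_id = "1") {
  stopifnot(is(mask, "LabelMask"), inherits(spec, "IntensitySpec"))
  n <- mask@n_cells
  if (n != length(clusters)) stop("one cluster label per cell required")
  A <- spec$archetypes
  if (!all(clusters %in% rownames(A)))
    stop("clusters without archetype: ",
         paste(setdiff(unique(clusters), rownames(A)), collapse = ", "))
  C <- ncol(A)
  chans <- colnames(A)
  gains <- if (length(spec$gains) == 1L)
    stats::setNames(rep(spec$gains, C), chans) else spec$gains[chans]
  H <- nrow(mask@labels); W <- ncol(mask@labels)
  .with_seed(spec$seed, {
    truth <- t(A[clusters, , drop = FALSE])          # channels x cells
    if (spec$sigma > 0)
      truth <- truth * matrix(stats::rlnorm(C * n, 0, spec$sigma), C, n)
    measured <- truth * gains
    P <- matrix(spec$background, C, H * W)           # channels x pixels
    idx <- which(mask@labels > 0L)
    lab <- mask@labels[idx]
    for (ch in seq_len(C)) P[ch, idx] <- P[ch, idx] + measured[ch, lab]
    if (spec$noise == "poisson")
      P[] <- stats::rpois(length(P), lambda = P)
    if (!is.null(spec$spillover)) P <- t(spec$spillover) %*% P
    data <- array(0, dim = c(C, H, W), dimnames = list(chans, NULL, NULL))
    for (ch in seq_len(C)) data[ch, , ] <- matrix(P[ch, ], H, W)
    stack <- new("ChannelStack", data = data, pixel_size_um = 1.0,
                 roi_id = roi_id, batch_id = batch_id)
  })
  feats <- extractFeatures(stack, mask)  # geometry columns (means unused)
  cd <- colData(feats)
  cd$true_cluster <- clusters
  dimnames(truth) <- list(chans, NULL)
  tt <- CellTable(truth, cd)
  list(stack = stack, truth = tt)
}

#' Generate a bimodal negative/positive intensity channel
#'
#' Stand-in for a gated marker channel: negatives drawn
#' Exponential(mean = neg_mean), positives LogNormal(median = pos_median,
#' log-sd = pos_sigma) — the right-skewed shapes characteristic of IMC
#' marker distributions at their typical scale. Used to exercise the Rd
#' cofactor titration with known population membership.
#'
#' @param n_neg,n_pos Population sizes (>= 2 each).
#' @param neg_mean Mean of the negative (background) population.
#' @param pos_median Median of the positive population.
#' @param pos_sigma Log-sd of the positive population.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{value} and \code{population}
#'   ("neg"/"pos").
#' @export
generateBimodalChannel <- function(n_neg, n_pos, neg_mean = 0.3,
                                   pos_median = 8, pos_sigma = 0.5,
                                   seed = 1) {
  if (n_neg < 2L || n_pos < 2L)
    stop("both populations need at least 2 cells")
  if (neg_mean <= 0 || pos_median <= 0 || pos_sigma <= 0)
    stop("distribution parameters must be positive")
  .with_seed(seed, {
    data.frame(
      value = c(stats::rexp(n_neg, rate = 1 / neg_mean),
                stats::rlnorm(n_pos, meanlog = log(pos_median),
                              sdlog = pos_sigma)),
      population = rep(c("neg", "pos"), c(n_neg, n_pos)))
  })
}

#' Simulate a tissue scene with a prescribed spatial relationship
#'
#' Convenience generators for benchmarking the neighborhood analysis:
#' \code{"interaction"} places a single central follicle whose cells are an
#' even mix of clusters A and B (so A and B are rare, interleaved, and
#' every A cell sits among B cells) in a background of filler cells C;
#' \code{"avoidance"} places two well-separated follicles of pure A and
#' pure C in filler F, so no A-C adjacency exists.
#'
#' @param type \code{"interaction"} or \code{"avoidance"}.
#' @param width,height,n_cells Scene geometry.
#' @param seed Integer seed.
#' @return As [generateLabelMask()].
#' @export
simulateInteractionScene <- function(type = c("interaction", "avoidance"),
                                     width = 256, height = 256,
                                     n_cells = 1200, seed = 1) {
  type <- match.arg(type)
  follicles <- if (type == "interaction") {
    list(list(center = c(width / 2, height / 2), radius = 0.2 * width,
              composition = c(A = 0.5, B = 0.5)))
  } else {
    list(list(center = c(0.22 * width, height / 2), radius = 0.16 * width,
              composition = c(A = 1)),
         list(center = c(0.78 * width, height / 2), radius = 0.16 * width,
              composition = c(C = 1)))
  }
  bg <- if (type == "interaction") c(C = 1) else c(F = 1)
  spec <- tissueSpec(width = width, height = height, n_cells = n_cells,
                     mean_area_um2 = 0.9 * width * height / n_cells / 1.25,
                     follicles = follicles, background_composition = bg,
                     seed = seed)
  generateLabelMask(spec)
}

#' Build a geometry-only CellTable from a generated scene
#'
#' Wraps the skeleton of [generateLabelMask()] as a
#' \linkS4class{CellTable} (zero channels) with \code{final_cluster} set to
#' the truth labels — the input shape the spatial stage consumes.
#'
#' @param sim Result of [generateLabelMask()] or
#'   [simulateInteractionScene()].
#' @param roi_id,batch_id Identifiers.
#' @return A \linkS4class{CellTable}.
#' @export
syntheticCellTable <- function(sim, roi_id = "sim", batch_id = "1") {
  cells <- sim$cells
  n <- nrow(cells)
  cd <- DataFrame(roi_id = rep(roi_id, n), batch_id = rep(batch_id, n),
                  cell_id = cells$cell_id,
                  centroid_x = cells$centroid_x,
                  centroid_y = cells$centroid_y,
                  area_um2 = cells$area_um2,
                  edge_flag = cells$edge_flag,
                  final_cluster = cells$true_cluster)
  CellTable(matrix(numeric(0), nrow = 0, ncol = n), cd)
}
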