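#' @include AllClasses.R utils.R
#' @importFrom Matrix sparseMatrix t crossprod
NULL

#' Neighborhood analysis configuration
#'
#' Bundles the tunable parameters of the spatial stage with the
#' field-standard defaults: a 5-pixel disc expansion (at IMC resolution
#' 1 px = 1 um), 100 label permutations with a 10% significance cutoff, a
#' 0.01 cluster occupancy threshold, removal of image-edge cells and of
#' objects outside 20-200 um^2 (under-/over-segmentation artifacts).
#'
#' @param distance_px Pixel expansion distance (>= 1).
#' @param method \code{"disc"} or \code{"bbox"}.
#' @param n_perm Number of random label permutations.
#' @param alpha Per-direction significance cutoff in (0, 0.5).
#' @param occupancy_threshold Minimum fraction of images a cluster must
#'   appear in (strictly exceeded) to enter the analysis.
#' @param min_area_um2,max_area_um2 Inclusive area bounds for
#'   [filterCells()].
#' @param drop_edge_cells Remove cells touching the image border.
#' @param seed Integer seed for the permutation null.
#' @return A validated list of class \code{"NeighborConfig"}.
#' @export
neighborConfig <- function(distance_px = 5L, method = c("disc", "bbox"),
                           n_perm = 100L, alpha = 0.10,
                           occupancy_threshold = 0.01,
                           min_area_um2 = 20, max_area_um2 = 200,
                           drop_edge_cells = TRUE, seed = NULL) {
  method <- match.arg(method)
  distance_px <- as.integer(distance_px)
  if (distance_px < 1L) stop("distance_px must be >= 1")
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 0.5)")
  if (min_area_um2 >= max_area_um2) stop("min_area_um2 must be < max_area_um2")
  if (occupancy_threshold < 0 || occupancy_threshold > 1)
    stop("occupancy_threshold must lie in [0, 1]")
  .assert_scalar_flag(drop_edge_cells, "drop_edge_cells")
  structure(list(distance_px = distance_px, method = method,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 occupancy_threshold = occupancy_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 drop_edge_cells = drop_edge_cells, seed = seed),
            class = "NeighborConfig")
}

#' Filter cells by area and edge contact
#'
#' Retains cells with \code{min_area_um2 <= area <= max_area_um2}
#' (inclusive) and, when \code{drop_edge_cells}, without border contact —
#' removing partial cells at the image edge and under-/over-segmented
#' objects before neighborhood analysis. Order is preserved; the retained
#' within-ROI cell ids are stored in \code{metadata(.)$kept_cell_ids}.
#'
#' @param ct A \linkS4class{CellTable}.
#' @param cfg A [neighborConfig()] (or any list with the area/edge fields).
#' @return The filtered \linkS4class{CellTable} (possibly empty).
#' @export
filterCells <- function(ct, cfg = neighborConfig()) {
  stopifnot(is(ct, "CellTable"))
  cd <- colData(ct)
  keep <- cd$area_um2 >= cfg$min_area_um2 & cd$area_um2 <= cfg$max_area_um2
  if (isTRUE(cfg$drop_edge_cells)) keep <- keep & !cd$edge_flag
  out <- ct[, keep]
  metadata(out)$kept_cell_ids <- cd$cell_id[keep]
  out
}

# Per-label pixel coordinates (1-based rows/cols) and bounding boxes.
.label_pixels <- function(mask) {
  H <- nrow(mask@labels)
  idx <- which(mask@labels > 0L)
  lab <- mask@labels[idx]
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  o <- order(lab)
  list(rows = split(r[o], lab[o]), cols = split(c[o], lab[o]))
}

#' Find neighboring cells by pixel expansion
#'
#' Two expansion geometries around each cell: \code{"disc"} — neighbors are
#' all other labels whose pixels intersect the morphological dilation of
#' the cell's pixel set by a Euclidean disc of radius \code{distance_px}
#' (equivalently, labels with any pixel-centre at distance <= d from the
#' cell; symmetric by construction); \code{"bbox"} — all labels with pixels
#' inside the cell's bounding box expanded by d on all four sides (the
#' classic approach; samples a larger, shape-blind region, overcounts
#' neighbors of elongated cells, and need not be symmetric).
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param cfg A [neighborConfig()]; \code{distance_px} and \code{method}
#'   are used.
#' @return An \linkS4class{AdjacencyMap}.
#' @export
findNeighbors <- function(mask, cfg = neighborConfig()) {
  stopifnot(is(mask, "LabelMask"))
  d <- cfg$distance_px
  n <- mask@n_cells
  if (n == 0L)
    return(new("AdjacencyMap", neighbors = list(), method = cfg$method,
               distance_px = d, n_cells = 0L))
  L <- mask@labels
  H <- nrow(L); W <- ncol(L)
  px <- .label_pixels(mask)
  nbrs <- vector("list", n)
  d2 <- as.numeric(d)^2
  for (i in seq_len(n)) {
    pr <- px$rows[[i]]; pc <- px$cols[[i]]
    r0 <- max(1L, min(pr) - d); r1 <- min(H, max(pr) + d)
    c0 <- max(1L, min(pc) - d); c1 <- min(W, max(pc) + d)
    win <- L[r0:r1, c0:c1, drop = FALSE]
    cand <- which(win > 0L & win != i)
    if (!length(cand)) { nbrs[[i]] <- integer(0); next }
    if (cfg$method == "bbox") {
      nbrs[[i]] <- sort(unique(win[cand]))
      next
    }
    wh <- r1 - r0 + 1L
    cr <- (cand - 1L) %% wh + r0
    cc <- (cand - 1L) %/% wh + c0
    # min squared pixel-centre distance from each candidate to the cell
    D2 <- outer(cr, pr, "-")^2 + outer(cc, pc, "-")^2
    hit <- .rowMins(D2) <= d2
    nbrs[[i]] <- sort(unique(win[cand[hit]]))
  }
  new("AdjacencyMap", neighbors = nbrs, method = cfg$method,
      distance_px = d, n_cells = n)
}

.rowMins <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) out <- pmin(out, m[, j])
  out
}

# Restrict an adjacency map to a subset of cell ids (reindexed 1..m).
# Removed cells are dropped both as centers and as neighbors, so filtering
# cannot create adjacencies through removed cells.
.subset_adjacency <- function(adj, keep_ids) {
  keep_ids <- sort(unique(as.integer(keep_ids)))
  newid <- integer(adj@n_cells)
  newid[keep_ids] <- seq_along(keep_ids)
  nb <- lapply(adj@neighbors[keep_ids], function(v) {
    v <- v[v %in% keep_ids]
    newid[v]
  })
  new("AdjacencyMap", neighbors = nb, method = adj@method,
      distance_px = adj@distance_px, n_cells = length(keep_ids))
}

#' Per-image permutation test for cluster interaction and avoidance
#'
#' For every ordered cluster pair (A, B) the statistic is the mean, over
#' cells of cluster A, of their neighbor count in cluster B. The null
#' shuffles the cluster labels uniformly over the image's cells (cluster
#' sizes preserved), \code{n_perm} times. The pair is called +1
#' (interaction) when the observed statistic strictly exceeds more than
#' \code{(1 - alpha) * n_perm} of the null draws, -1 (avoidance) when it
#' falls strictly below more than that many, and 0 otherwise — so a
#' permutation-invariant statistic (e.g. a single cluster) is always 0.
#'
#' @param labels Cluster label per cell of \code{adj} (character or
#'   factor).
#' @param adj An \linkS4class{AdjacencyMap} over the same cells.
#' @param cfg A [neighborConfig()]; \code{n_perm}, \code{alpha} and
#'   \code{seed} are used.
#' @return A list with \code{ternary} (clusters x clusters matrix in
#'   {-1, 0, 1} over the clusters present in this image), \code{observed},
#'   and the empirical null quantiles \code{null_lo}/\code{null_hi}.
#' @export
neighborhoodPermutationTest <- function(labels, adj, cfg = neighborConfig()) {
  stopifnot(is(adj, "AdjacencyMap"))
  n <- adj@n_cells
  if (length(labels) != n) stop("labels must cover all cells in adj")
  f <- droplevels(factor(labels))
  K <- nlevels(f)
  cl <- levels(f)
  li <- as.integer(f)
  counts <- tabulate(li, nbins = K)

  deg <- lengths(adj@neighbors)
  M <- sparseMatrix(i = rep(seq_len(n), deg),
                    j = unlist(adj@neighbors, use.names = FALSE),
                    x = 1, dims = c(n, n))
  stat_for <- function(lv) {
    Ind <- sparseMatrix(i = seq_len(n), j = lv, x = 1, dims = c(n, K))
    S <- as.matrix(crossprod(Ind, M %*% Ind))  # K x K total neighbor counts
    S / counts                                 # mean per center cell
  }
  obs <- stat_for(li)
  dimnames(obs) <- list(center = cl, neighbor = cl)

  n_gt <- matrix(0L, K, K)
  n_lt <- matrix(0L, K, K)
  null_draws <- array(NA_real_, dim = c(cfg$n_perm, K, K))
  .with_seed(cfg$seed, {
    for (p in seq_len(cfg$n_perm)) {
      sp <- stat_for(li[sample.int(n)])
      n_gt <- n_gt + (obs > sp)
      n_lt <- n_lt + (obs < sp)
      null_draws[p, , ] <- sp
    }
  })
  thr <- (1 - cfg$alpha) * cfg$n_perm
  tern <- matrix(0L, K, K, dimnames = dimnames(obs))
  tern[n_gt > thr] <- 1L
  tern[n_lt > thr] <- -1L
  qlo <- apply(null_draws, c(2, 3), .pctile, p = 100 * cfg$alpha)
  qhi <- apply(null_draws, c(2, 3), .pctile, p = 100 * (1 - cfg$alpha))
  dimnames(qlo) <- dimnames(qhi) <- dimnames(obs)
  list(ternary = tern, observed = obs, null_lo = qlo, null_hi = qhi)
}

#' Occupancy filter for clusters entering neighborhood analysis
#'
#' Retains clusters whose presence fraction (share of images containing at
#' least one cell of the cluster) strictly exceeds the threshold. With the
#' default threshold of 0.01, clusters present in every image always pass.
#'
#' @param presence Named numeric vector of per-cluster presence fractions
#'   in [0, 1].
#' @param threshold Occupancy cutoff.
#' @return Character vector of retained cluster names.
#' @export
occupancyFilter <- function(presence, threshold = 0.01) {
  if (any(presence < 0 | presence > 1)) stop("presence fractions must lie in [0, 1]")
  names(presence)[presence > threshold]
}

#' Aggregate per-image ternary interaction calls
#'
#' Entrywise mean of the per-image +1/0/-1 calls over the images in which
#' the pair is defined (both clusters present), giving the proportion
#' heatmap in [-1, 1]: 1 means every image showed a significant positive
#' interaction, -1 every image a significant avoidance. Pairs defined in no
#' image are NA.
#'
#' @param ternaries List of per-image ternary matrices (as returned in the
#'   \code{ternary} element of [neighborhoodPermutationTest()]), or the
#'   per-image result lists themselves.
#' @param clusters Optional cluster universe (default: union over images).
#' @return An \linkS4class{InteractionResult}.
#' @export
aggregateInteractions <- function(ternaries, clusters = NULL) {
  if (length(ternaries) == 0L) stop("at least one image is required")
  mats <- lapply(ternaries, function(x) if (is.list(x)) x$ternary else x)
  obs <- lapply(ternaries, function(x) if (is.list(x)) x$observed else NULL)
  if (is.null(clusters))
    clusters <- sort(unique(unlist(lapply(mats, rownames))))
  acc <- matrix(0, length(clusters), length(clusters),
                dimnames = list(center = clusters, neighbor = clusters))
  cnt <- matrix(0L, length(clusters), length(clusters))
  for (m in mats) {
    cc <- intersect(clusters, rownames(m))
    ii <- match(cc, clusters)
    acc[ii, ii] <- acc[ii, ii] + m[cc, cc]
    cnt[ii, ii] <- cnt[ii, ii] + 1L
  }
  agg <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  dimnames(agg) <- dimnames(acc)
  if (is.null(names(mats))) names(mats) <- paste0("image", seq_along(mats))
  new("InteractionResult", ternary = mats, aggregate = agg,
      observed = Filter(Negate(is.null), obs), clusters = clusters)
}

#' End-to-end spatial neighborhood analysis over a set of images
#'
#' For each image: detect neighbors on the full mask, drop cells failing
#' the area/edge filter (both as centers and as neighbors), run the
#' permutation test on the final cluster labels, then apply the occupancy
#' filter across images and aggregate the ternary calls. Per-image
#' permutation seeds are derived deterministically from \code{cfg$seed}.
#'
#' @param tables Named list of per-image \linkS4class{CellTable}s with
#'   \code{final_cluster} populated.
#' @param masks List of matching \linkS4class{LabelMask}s (same order).
#' @param cfg A [neighborConfig()].
#' @return An \linkS4class{InteractionResult}.
#' @export
spatialInteractionAnalysis <- function(tables, masks, cfg = neighborConfig()) {
  stopifnot(length(tables) == length(masks), length(tables) >= 1L)
  slices <- vector("list", length(tables))
  names(slices) <- names(tables)
  kept_labels <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    ct <- tables[[k]]
    adj <- findNeighbors(masks[[k]], cfg)
    fct <- filterCells(ct, cfg)
    if (ncol(fct) == 0L) next
    sub <- .subset_adjacency(adj, metadata(fct)$kept_cell_ids)
    cfg_k <- cfg
    cfg_k$seed <- if (is.null(cfg$seed)) NULL else cfg$seed + k
    labs <- as.character(clusterLabels(fct, "final"))
    slices[[k]] <- neighborhoodPermutationTest(labs, sub, cfg_k)
    kept_labels[[k]] <- unique(labs)
  }
  ok <- !vapply(slices, is.null, logical(1))
  if (!any(ok)) stop("no image retained any cells after filtering")
  slices <- slices[ok]; kept_labels <- kept_labels[ok]
  universe <- sort(unique(unlist(kept_labels)))
  presence <- vapply(universe, function(cl)
    mean(vapply(kept_labels, function(x) cl %in% x, logical(1))), numeric(1))
  retained <- occupancyFilter(presence, cfg$occupancy_threshold)
  slices <- lapply(slices, function(s) {
    cc <- intersect(rownames(s$ternary), retained)
    s$ternary <- s$ternary[cc, cc, drop = FALSE]
    s$observed <- s$observed[cc, cc, drop = FALSE]
    s
  })
  aggregateInteractions(slices, clusters = retained)
}
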