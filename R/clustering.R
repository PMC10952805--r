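#' @include AllClasses.R utils.R
NULL

#' Train a self-organizing map on cell intensities
#'
#' Online SOM with a gaussian neighborhood kernel on a rectangular grid
#' (default 10 x 10 = 100 nodes, the conventional first-stage partition for
#' cytometry data). The learning rate and neighborhood radius decay
#' linearly over all presentation steps; the codebook is initialized from
#' randomly sampled data rows and the presentation order is reshuffled each
#' epoch, so the fit is fully reproducible given \code{seed}.
#'
#' @param matrix Cells x channels numeric matrix — typically the
#'   transformed + normalized intensities of the clustering channels
#'   (\code{t(normalizedIntensity(ct)[clusteringChannels(panel), ])}).
#' @param rows,cols SOM grid dimensions.
#' @param epochs Passes over the data (default 10).
#' @param alpha Start/end learning rate.
#' @param radius Start/end neighborhood radius; defaults to
#'   \code{max(rows, cols)/2} decaying to 0.5.
#' @param seed Integer seed (required for reproducibility).
#' @return A \linkS4class{SOMModel}; cell assignments are to the nearest
#'   codebook vector after training, and the mean distance to it is the
#'   reported quantization error.
#' @export
trainSOM <- function(matrix, rows = 10, cols = 10, epochs = 10,
                     alpha = c(0.05, 0.01), radius = NULL, seed = 1) {
  X <- as.matrix(matrix)
  if (nrow(X) < 2L) stop("at least 2 cells are required")
  storage.mode(X) <- "double"
  rows <- as.integer(rows); cols <- as.integer(cols)
  m <- rows * cols
  if (is.null(radius)) radius <- c(max(rows, cols) / 2, 0.5)
  .with_seed(seed, {
    init_idx <- sample.int(nrow(X), m, replace = nrow(X) < m)
    order <- as.integer(unlist(lapply(seq_len(epochs),
                                      function(e) sample.int(nrow(X)))))
  })
  fit <- .som_train_cpp(X, X[init_idx, , drop = FALSE], order, rows, cols,
                        alpha[1], alpha[2], radius[1], radius[2])
  cb <- fit$codebook
  colnames(cb) <- colnames(X)
  new("SOMModel", codebook = cb, grid_rows = rows, grid_cols = cols,
      assignments = fit$assignments, quant_error = fit$quant_error,
      config = list(epochs = epochs, alpha = alpha, radius = radius,
                    seed = seed))
}

#' Merge SOM nodes into consensus metaclusters
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage by default) of the codebook vectors, cut at \code{n_meta} groups
#' — deterministic, and the direct reading of "consensus clusters based on
#' hierarchical clustering". The conventional reduction is 100 SOMs to 30
#' consensus clusters.
#'
#' @param model A \linkS4class{SOMModel}.
#' @param n_meta Number of consensus clusters (default 30).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A \linkS4class{MetaclusterMap}.
#' @export
consensusMetacluster <- function(model, n_meta = 30, linkage = "average") {
  stopifnot(is(model, "SOMModel"))
  n_meta <- as.integer(n_meta)
  if (n_meta < 1L) stop("n_meta must be at least 1")
  occupied <- length(unique(model@assignments))
  if (length(model@assignments) && n_meta > occupied)
    stop("n_meta (", n_meta, ") exceeds the ", occupied,
         " non-empty SOM nodes")
  cb <- model@codebook
  if (n_meta == nrow(cb)) {
    mapping <- seq_len(nrow(cb))
  } else {
    hc <- stats::hclust(stats::dist(cb), method = linkage)
    mapping <- stats::cutree(hc, k = n_meta)
  }
  # renumber in order of first appearance for stable contiguous ids
  mapping <- as.integer(factor(mapping, levels = unique(mapping)))
  new("MetaclusterMap", mapping = mapping, n_meta = n_meta,
      linkage = linkage)
}

#' Attach SOM and consensus cluster assignments to a CellTable
#'
#' Sets \code{som_id} from the model and \code{csom_id} = map[som_id];
#' every cell receives exactly one label at each level.
#'
#' @param ct A \linkS4class{CellTable} whose columns are the cells the
#'   model was trained on (same order).
#' @param model A \linkS4class{SOMModel}.
#' @param map A \linkS4class{MetaclusterMap}.
#' @return The updated \linkS4class{CellTable}.
#' @export
assignMetaclusters <- function(ct, model, map) {
  stopifnot(is(ct, "CellTable"), is(model, "SOMModel"),
            is(map, "MetaclusterMap"))
  if (length(model@assignments) != ncol(ct))
    stop("model was trained on ", length(model@assignments),
         " cells but the table has ", ncol(ct))
  som <- model@assignments
  if (max(som) > length(map@mapping))
    stop("unmapped som_id: ", max(som))
  colData(ct)$som_id <- som
  colData(ct)$csom_id <- map@mapping[som]
  ct
}

#' Per-cluster marker median heatmap
#'
#' Entry (channel, cluster) is the median of that channel over the
#' cluster's cells. \code{normalize = "column"} min-max rescales each
#' cluster's column to [0, 1] (the display convention for per-cluster
#' marker patterns); \code{"row"} rescales per channel; \code{"none"}
#' returns raw medians. Cluster frequencies (share of all cells) are
#' attached as the \code{"frequencies"} attribute. Empty clusters (possible
#' when \code{clusters} is supplied explicitly) yield NaN columns.
#'
#' @param ct A \linkS4class{CellTable}.
#' @param level Cluster level: \code{"csom"} (default) or \code{"final"} or
#'   \code{"som"}.
#' @param channels Channels to include (default: clustering channels if
#'   flagged in rowData, else all).
#' @param normalize \code{"column"}, \code{"row"} or \code{"none"}.
#' @param assay_name Assay to summarize (default \code{"normalized"}).
#' @return Channels x clusters matrix with a \code{"frequencies"}
#'   attribute.
#' @export
clusterMarkerHeatmap <- function(ct, level = "csom", channels = NULL,
                                 normalize = c("column", "row", "none"),
                                 assay_name = "normalized") {
  stopifnot(is(ct, "CellTable"))
  normalize <- match.arg(normalize)
  cl <- clusterLabels(ct, level)
  Y <- assay(ct, assay_name)
  if (is.null(channels)) {
    channels <- if ("use_for_clustering" %in% colnames(rowData(ct)) &&
                    any(rowData(ct)$use_for_clustering))
      rownames(ct)[rowData(ct)$use_for_clustering] else rownames(ct)
  }
  cl <- factor(cl)
  H <- matrix(NA_real_, nrow = length(channels), ncol = nlevels(cl),
              dimnames = list(channels, levels(cl)))
  for (g in levels(cl)) {
    j <- cl == g
    H[, g] <- apply(Y[channels, j, drop = FALSE], 1, stats::median)
  }
  rescale <- function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  }
  H <- switch(normalize,
              column = apply(H, 2, rescale),
              row = t(apply(H, 1, rescale)),
              none = H)
  if (is.null(dim(H)))   # single channel collapsed by apply
    H <- matrix(H, nrow = length(channels),
                dimnames = list(channels, levels(cl)))
  attr(H, "frequencies") <- as.numeric(table(cl)) / length(cl)
  names(attr(H, "frequencies")) <- levels(cl)
  H
}

#' Apply a manual cluster merge table
#'
#' Maps every consensus cluster id to a user-authored final cluster name
#' (the expert-annotation step that merges phenotypically identical
#' consensus clusters). The merge table must cover every observed
#' \code{csom_id}.
#'
#' @param ct A \linkS4class{CellTable} with \code{csom_id} populated.
#' @param merge Named vector or two-column data.frame (csom_id,
#'   final_cluster).
#' @return The table with a \code{final_cluster} column.
#' @export
mergeClusters <- function(ct, merge) {
  stopifnot(is(ct, "CellTable"))
  if (!"csom_id" %in% colnames(colData(ct)))
    stop("csom_id column missing; run assignMetaclusters() first")
  if (is.data.frame(merge)) {
    stopifnot(ncol(merge) >= 2L)
    map <- stats::setNames(as.character(merge[[2]]), as.character(merge[[1]]))
  } else {
    map <- stats::setNames(as.character(merge), names(merge))
  }
  ids <- as.character(colData(ct)$csom_id)
  missing <- setdiff(unique(ids), names(map))
  if (length(missing))
    stop("merge table missing csom_id(s): ", paste(missing, collapse = ", "))
  colData(ct)$final_cluster <- unname(map[ids])
  ct
}

#' Cluster recovery score (adjusted Rand index)
#'
#' Chance-corrected agreement between a predicted and a reference
#' partition, in [-1, 1] (1 = identical up to label names, ~0 = chance).
#' Used to benchmark how faithfully the SOM + consensus pipeline recovers
#' known cell types, e.g. across segmentation qualities.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
clusterRecoveryScore <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(predicted, truth)
}
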