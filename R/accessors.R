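#' @include AllClasses.R
NULL

# ---- generics ---------------------------------------------------------------

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @export
setGeneric("clusteringChannels", function(x) standardGeneric("clusteringChannels"))
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("rawIntensity", function(x) standardGeneric("rawIntensity"))
#' @export
setGeneric("transformedIntensity", function(x) standardGeneric("transformedIntensity"))
#' @export
setGeneric("normalizedIntensity", function(x) standardGeneric("normalizedIntensity"))
#' @export
setGeneric("cellInfo", function(x) standardGeneric("cellInfo"))
#' @export
setGeneric("clusterLabels", function(x, level = "final") standardGeneric("clusterLabels"))
#' @export
setGeneric("neighborList", function(x) standardGeneric("neighborList"))
#' @export
setGeneric("medianNN", function(x) standardGeneric("medianNN"))
#' @export
setGeneric("rdOptimum", function(x) standardGeneric("rdOptimum"))
#' @export
setGeneric("interactionAggregate", function(x) standardGeneric("interactionAggregate"))

# ---- Panel ------------------------------------------------------------------

#' Accessors for Panel objects
#'
#' \code{nChannels} returns the number of channels; \code{markerNames} the
#' marker names (all channels, in panel order); \code{clusteringChannels}
#' the marker names flagged for clustering.
#'
#' @param x A \linkS4class{Panel}.
#' @rdname Panel-accessors
#' @export
setMethod("nChannels", "Panel", function(x) nrow(x@channels))

#' @rdname Panel-accessors
#' @export
setMethod("markerNames", "Panel", function(x) as.character(x@channels$marker))

#' @rdname Panel-accessors
#' @export
setMethod("clusteringChannels", "Panel", function(x)
  as.character(x@channels$marker[x@channels$use_for_clustering & !x@channels$blank]))

#' @export
setMethod("show", "Panel", function(object) {
  ch <- object@channels
  cat("Panel with", nrow(ch), "channels (",
      sum(!ch$blank), "non-blank,", sum(ch$use_for_clustering & !ch$blank),
      "for clustering )\n")
  cat("  markers:", paste(utils::head(ch$marker, 8), collapse = ", "),
      if (nrow(ch) > 8) "...", "\n")
})

# ---- ChannelStack -----------------------------------------------------------

#' Accessors for ChannelStack objects
#'
#' @param x A \linkS4class{ChannelStack}.
#' @rdname ChannelStack-accessors
#' @export
setMethod("channelData", "ChannelStack", function(x) x@data)

#' @rdname ChannelStack-accessors
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixel_size_um)

#' @rdname ChannelStack-accessors
#' @export
setMethod("nChannels", "ChannelStack", function(x) dim(x@data)[1L])

#' @export
setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@data)
  cat("ChannelStack:", d[1], "channels,", d[2], "x", d[3], "px @",
      object@pixel_size_um, "um/px\n")
  cat("  roi:", object@roi_id, " batch:", object@batch_id, "\n")
})

# ---- LabelMask --------------------------------------------------------------

#' Accessors for LabelMask objects
#'
#' @param x A \linkS4class{LabelMask}.
#' @rdname LabelMask-accessors
#' @export
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' @rdname LabelMask-accessors
#' @export
setMethod("nCells", "LabelMask", function(x) x@n_cells)

#' @export
setMethod("show", "LabelMask", function(object) {
  cat("LabelMask:", nrow(object@labels), "x", ncol(object@labels), "px,",
      object@n_cells, "cells\n")
})

# ---- CellTable --------------------------------------------------------------

#' Construct a CellTable
#'
#' Low-level constructor assembling a \linkS4class{CellTable} from a raw
#' channel-by-cell intensity matrix and per-cell metadata. Most users obtain
#' CellTables from [extractFeatures()].
#'
#' @param raw Numeric channels x cells matrix of mean intensities
#'   (rownames = marker names).
#' @param cellData A data.frame/DataFrame with one row per cell providing at
#'   least roi_id, batch_id, cell_id, centroid_x, centroid_y, area_um2 and
#'   edge_flag.
#' @param channelData Optional per-channel metadata (metal, marker,
#'   use_for_clustering, blank).
#' @return A \linkS4class{CellTable}.
#' @export
CellTable <- function(raw, cellData, channelData = NULL) {
  raw <- as.matrix(raw)
  cd <- DataFrame(cellData)
  args <- list(assays = list(raw = raw), colData = cd)
  if (!is.null(channelData)) args$rowData <- DataFrame(channelData)
  se <- do.call(SingleCellExperiment, args)
  new("CellTable", se)
}

#' Accessors for CellTable objects
#'
#' \code{rawIntensity}, \code{transformedIntensity} and
#' \code{normalizedIntensity} return the corresponding channel x cell assay;
#' \code{cellInfo} returns the per-cell metadata; \code{clusterLabels}
#' returns cluster assignments at level \code{"som"}, \code{"csom"} or
#' \code{"final"}; \code{nCells} the number of cells.
#'
#' @param x A \linkS4class{CellTable}.
#' @param level Cluster level for \code{clusterLabels}.
#' @rdname CellTable-accessors
#' @export
setMethod("rawIntensity", "CellTable", function(x) assay(x, "raw"))

#' @rdname CellTable-accessors
#' @export
setMethod("transformedIntensity", "CellTable", function(x) {
  if (!"transformed" %in% assayNames(x))
    stop("no 'transformed' assay; run arcsinhTransform() first")
  assay(x, "transformed")
})

#' @rdname CellTable-accessors
#' @export
setMethod("normalizedIntensity", "CellTable", function(x) {
  if (!"normalized" %in% assayNames(x))
    stop("no 'normalized' assay; run zscoreNormalize() first")
  assay(x, "normalized")
})

#' @rdname CellTable-accessors
#' @export
setMethod("cellInfo", "CellTable", function(x) colData(x))

#' @rdname CellTable-accessors
#' @export
setMethod("nCells", "CellTable", function(x) ncol(x))

#' @rdname CellTable-accessors
#' @export
setMethod("clusterLabels", "CellTable", function(x, level = "final") {
  col <- switch(match.arg(level, c("som", "csom", "final")),
                som = "som_id", csom = "csom_id", final = "final_cluster")
  if (!col %in% colnames(colData(x)))
    stop("cluster column '", col, "' not present")
  colData(x)[[col]]
})

#' @export
setMethod("show", "CellTable", function(object) {
  cat("CellTable:", nrow(object), "channels x", ncol(object), "cells\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (ncol(object)) {
    cat("  ROIs:", length(unique(colData(object)$roi_id)),
        " batches:", length(unique(colData(object)$batch_id)), "\n")
    cls <- intersect(c("som_id", "csom_id", "final_cluster"),
                     colnames(colData(object)))
    if (length(cls)) cat("  cluster columns:", paste(cls, collapse = ", "), "\n")
  }
})

# ---- SOM / metaclusters -----------------------------------------------------

#' @export
setMethod("show", "SOMModel", function(object) {
  cat("SOMModel:", object@grid_rows, "x", object@grid_cols, "grid,",
      ncol(object@codebook), "channels,", length(object@assignments),
      "cells\n  quantization error:",
      format(object@quant_error, digits = 4), "\n")
})

#' @export
setMethod("show", "MetaclusterMap", function(object) {
  cat("MetaclusterMap:", length(object@mapping), "SOM nodes ->",
      length(unique(object@mapping)), "consensus clusters (",
      object@linkage, "linkage )\n")
})

#' @rdname RdCurve-class
#' @param x An \linkS4class{RdCurve}.
#' @export
setMethod("rdOptimum", "RdCurve", function(x) x@optimum)

#' @export
setMethod("show", "RdCurve", function(object) {
  cat("RdCurve over", length(object@cofactors), "cofactors; optimum =",
      object@optimum, "\n")
})

# ---- spatial ----------------------------------------------------------------

#' @rdname AdjacencyMap-class
#' @param x An \linkS4class{AdjacencyMap}.
#' @export
setMethod("neighborList", "AdjacencyMap", function(x) x@neighbors)

#' Median nearest-neighbor count
#'
#' The median over cells of the number of detected neighbors — the metric
#' used to benchmark pixel-expansion settings (disc at 5 px gives ~6-8
#' neighbors in densely packed tissue; bounding boxes overcount).
#'
#' @param x An \linkS4class{AdjacencyMap}.
#' @return A single number.
#' @rdname medianNN
#' @export
setMethod("medianNN", "AdjacencyMap", function(x) {
  if (x@n_cells == 0L) stop("empty adjacency map")
  stats::median(lengths(x@neighbors))
})

#' @export
setMethod("show", "AdjacencyMap", function(object) {
  cat("AdjacencyMap (", object@method, ", d =", object@distance_px, "px ):",
      object@n_cells, "cells\n")
  if (object@n_cells)
    cat("  median NN:", stats::median(lengths(object@neighbors)), "\n")
})

#' @rdname InteractionResult-class
#' @param x An \linkS4class{InteractionResult}.
#' @export
setMethod("interactionAggregate", "InteractionResult", function(x) x@aggregate)

#' @export
setMethod("show", "InteractionResult", function(object) {
  cat("InteractionResult:", length(object@ternary), "images,",
      length(object@clusters), "clusters\n")
  a <- object@aggregate
  if (length(a))
    cat("  aggregate range: [", min(a, na.rm = TRUE), ",",
        max(a, na.rm = TRUE), "]\n")
})
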