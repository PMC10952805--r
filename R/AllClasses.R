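#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<- rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Panel: ordered channel descriptors for an IMC acquisition
#'
#' A \code{Panel} ties the planes of a multilevel TIFF to metals and marker
#' names, and records which channels enter clustering and which are blank
#' (open-collection QC) channels.
#'
#' @slot channels A \linkS4class{DataFrame} with columns \code{plane_index}
#'   (0-based plane in the source TIFF), \code{metal}, \code{marker},
#'   \code{use_for_clustering} and \code{blank}.
#' @seealso [readPanel()]
#' @export
setClass("Panel", slots = c(channels = "DataFrame"))

setValidity("Panel", function(object) {
  ch <- object@channels
  need <- c("plane_index", "metal", "marker", "use_for_clustering", "blank")
  if (!all(need %in% colnames(ch)))
    return(paste("missing panel columns:",
                 paste(setdiff(need, colnames(ch)), collapse = ", ")))
  if (nrow(ch) == 0L) return("panel has no channels")
  if (anyDuplicated(ch$plane_index))
    return("duplicate plane_index values")
  if (any(ch$plane_index < 0L))
    return("plane_index values must be non-negative")
  if (!any(!ch$blank))
    return("panel must contain at least one non-blank channel")
  if (anyDuplicated(ch$marker[!ch$blank]))
    return("duplicate marker names among non-blank channels")
  TRUE
})

#' ChannelStack: a multichannel IMC image
#'
#' Holds the pixel data of one ROI as a C x H x W numeric array (one plane
#' per panel channel, ordered as in the \linkS4class{Panel}), together with
#' the physical pixel size and ROI/batch identifiers. IMC acquisitions are
#' 1 um/pixel.
#'
#' @slot data Numeric C x H x W array, all values >= 0.
#' @slot pixel_size_um Pixel edge length in micrometers (default 1).
#' @slot roi_id,batch_id Identifiers carried into the cell table.
#' @seealso [readImage()], [capHotPixels()], [extractFeatures()]
#' @export
setClass("ChannelStack",
         slots = c(data = "array", pixel_size_um = "numeric",
                   roi_id = "character", batch_id = "character"))

setValidity("ChannelStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a C x H x W array")
  if (any(dim(d)[2:3] < 1L)) return("image height and width must be >= 1")
  if (anyNA(d) || any(d < 0)) return("all intensities must be finite and >= 0")
  if (length(object@pixel_size_um) != 1L || object@pixel_size_um <= 0)
    return("pixel_size_um must be a single positive number")
  TRUE
})

#' LabelMask: an integer segmentation mask
#'
#' Pixel value 0 is background; cells are labelled exactly 1..n_cells
#' (sparse label images are relabelled on ingestion, see [readMask()]).
#'
#' @slot labels Integer H x W matrix.
#' @slot n_cells Number of labelled cells.
#' @slot mapping Named integer vector recording the original label for each
#'   new contiguous label (traceability of the relabelling).
#' @export
setClass("LabelMask",
         slots = c(labels = "matrix", n_cells = "integer",
                   mapping = "integer"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (!is.integer(l)) return("labels must be an integer matrix")
  if (anyNA(l) || any(l < 0L)) return("labels must be non-negative integers")
  pos <- sort(unique(l[l > 0L]))
  if (!identical(pos, seq_len(object@n_cells)))
    return("cell labels must be exactly 1..n_cells")
  TRUE
})

#' CellTable: the central cell-by-feature container
#'
#' A \linkS4class{SingleCellExperiment} with channels as rows and cells as
#' columns. The assay \code{"raw"} holds per-cell mean intensities; the
#' optional assays \code{"compensated"}, \code{"transformed"} (arcsinh),
#' \code{"normalized"} (Z-score) and \code{"scaled01"} (0-1 scaling) are
#' added by the corresponding pipeline stages. Per-cell metadata live in
#' \code{colData}: \code{roi_id}, \code{batch_id}, \code{cell_id} (1-based
#' within each ROI), \code{centroid_x}/\code{centroid_y} (0-based pixel
#' coordinates, origin top-left, x = column, y = row), \code{area_um2} and
#' \code{edge_flag}; clustering adds \code{som_id}, \code{csom_id} and
#' \code{final_cluster}. Channel metadata (metal, marker, clustering/blank
#' flags) live in \code{rowData}.
#'
#' @seealso [extractFeatures()], [CellTable()]
#' @export
setClass("CellTable", contains = "SingleCellExperiment")

.celltable_required_cols <- c("roi_id", "batch_id", "cell_id",
                              "centroid_x", "centroid_y", "area_um2",
                              "edge_flag")

setValidity("CellTable", function(object) {
  if (ncol(object) == 0L) return(TRUE)
  if (!"raw" %in% assayNames(object)) return("assay 'raw' is required")
  cd <- colData(object)
  miss <- setdiff(.celltable_required_cols, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(paste(cd$roi_id, cd$cell_id, sep = "\r")))
    return("(roi_id, cell_id) pairs must be unique")
  if (any(!is.finite(cd$area_um2)) || any(cd$area_um2 <= 0))
    return("area_um2 must be positive")
  raw <- assay(object, "raw")
  if (any(raw < 0, na.rm = TRUE)) return("raw intensities must be >= 0")
  for (cl in c("som_id", "csom_id", "final_cluster"))
    if (cl %in% colnames(cd) && anyNA(cd[[cl]]))
      return(paste0("cluster column '", cl,
                    "' must be fully populated when present"))
  TRUE
})

#' SOMModel: a trained self-organizing map
#'
#' @slot codebook Node x channel matrix of prototype vectors.
#' @slot grid_rows,grid_cols SOM grid dimensions (default 10 x 10 = 100
#'   nodes).
#' @slot assignments Integer vector mapping each training cell to its best
#'   matching node (1..grid_rows*grid_cols).
#' @slot quant_error Mean Euclidean distance of cells to their node.
#' @slot config Training configuration (epochs, learning rate and radius
#'   schedules, seed).
#' @export
setClass("SOMModel",
         slots = c(codebook = "matrix", grid_rows = "integer",
                   grid_cols = "integer", assignments = "integer",
                   quant_error = "numeric", config = "list"))

setValidity("SOMModel", function(object) {
  m <- object@grid_rows * object@grid_cols
  if (nrow(object@codebook) != m)
    return("codebook must have grid_rows * grid_cols rows")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > m))
    return("assignments out of node range")
  TRUE
})

#' MetaclusterMap: SOM node to consensus cluster assignment
#'
#' @slot mapping Integer vector: csom id for each som node id.
#' @slot n_meta Requested number of consensus clusters.
#' @slot linkage Agglomeration method used on the codebook.
#' @export
setClass("MetaclusterMap",
         slots = c(mapping = "integer", n_meta = "integer",
                   linkage = "character"))

setValidity("MetaclusterMap", function(object) {
  if (anyNA(object@mapping)) return("mapping must be total")
  k <- length(unique(object@mapping))
  if (k > object@n_meta)
    return("more distinct metaclusters than n_meta")
  if (!identical(sort(unique(object@mapping)), seq_len(k)))
    return("metacluster ids must be contiguous 1..m")
  TRUE
})

#' RdCurve: Fisher discrimination ratio across an arcsinh cofactor grid
#'
#' @slot cofactors Tested cofactors (positive).
#' @slot rd_values Rd at each cofactor.
#' @slot optimum The cofactor maximizing Rd (ties broken toward the
#'   smallest cofactor).
#' @seealso [titrateCofactor()]
#' @export
setClass("RdCurve",
         slots = c(cofactors = "numeric", rd_values = "numeric",
                   optimum = "numeric"))

setValidity("RdCurve", function(object) {
  if (length(object@cofactors) != length(object@rd_values))
    return("cofactors and rd_values must have equal length")
  if (any(object@cofactors <= 0)) return("cofactors must be positive")
  if (!object@optimum %in% object@cofactors)
    return("optimum must be one of the tested cofactors")
  TRUE
})

#' AdjacencyMap: per-cell neighbor lists
#'
#' Produced by [findNeighbors()] for one label mask at a given pixel
#' expansion. Disc adjacency is symmetric; bounding-box adjacency need not
#' be.
#'
#' @slot neighbors List (one integer vector per cell) of neighboring cell
#'   ids; never contains the cell itself.
#' @slot method \code{"disc"} or \code{"bbox"}.
#' @slot distance_px Pixel expansion distance.
#' @slot n_cells Number of cells covered.
#' @export
setClass("AdjacencyMap",
         slots = c(neighbors = "list", method = "character",
                   distance_px = "integer", n_cells = "integer"))

setValidity("AdjacencyMap", function(object) {
  if (length(object@neighbors) != object@n_cells)
    return("one neighbor list per cell required")
  for (i in seq_along(object@neighbors))
    if (i %in% object@neighbors[[i]]) return("self-neighbors are not allowed")
  if (!object@method %in% c("disc", "bbox"))
    return("method must be 'disc' or 'bbox'")
  TRUE
})

#' InteractionResult: per-image ternary interaction calls and their
#' cross-image aggregate
#'
#' For every ordered (center cluster, neighbor cluster) pair each image
#' contributes +1 (significant interaction), -1 (significant avoidance) or
#' 0 (indifference); the aggregate is the mean over images in which the
#' pair is defined, ranging from 1 (all images interact) to -1 (all images
#' avoid).
#'
#' @slot ternary Named list of per-image ternary matrices.
#' @slot aggregate Cluster x cluster matrix in [-1, 1] (NA where a pair is
#'   defined in no image).
#' @slot observed Named list of per-image observed statistics (mean
#'   neighbor counts).
#' @slot clusters Cluster universe of the aggregate.
#' @export
setClass("InteractionResult",
         slots = c(ternary = "list", aggregate = "matrix",
                   observed = "list", clusters = "character"))

setValidity("InteractionResult", function(object) {
  a <- object@aggregate
  if (length(a) && any(abs(a[!is.na(a)]) > 1 + 1e-12))
    return("aggregate values must lie in [-1, 1]")
  TRUE
})
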