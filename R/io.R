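#' @include AllClasses.R utils.R
NULL

#' Read a panel CSV
#'
#' The panel ties TIFF planes to metals and markers. Expected header columns:
#' \code{plane_index} (0-based), \code{metal}, \code{marker},
#' \code{use_for_clustering}, \code{blank} (logical or 0/1).
#'
#' @param path Path to the panel CSV.
#' @return A \linkS4class{Panel}; row order of the file is preserved.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write.csv(data.frame(plane_index = 0:1, metal = c("193Ir", "170Er"),
#'                      marker = c("DNA", "CD3"),
#'                      use_for_clustering = c(FALSE, TRUE),
#'                      blank = FALSE), p, row.names = FALSE)
#' readPanel(p)
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plane_index", "metal", "marker", "use_for_clustering", "blank")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("panel format error: missing columns ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$plane_index))
    stop("panel format error: duplicate plane_index values")
  ch <- DataFrame(plane_index = as.integer(df$plane_index),
                  metal = as.character(df$metal),
                  marker = as.character(df$marker),
                  use_for_clustering = as.logical(df$use_for_clustering),
                  blank = as.logical(df$blank))
  new("Panel", channels = ch)
}

# Read all planes of a (possibly multilevel) TIFF as a list of numeric
# matrices with original sample values (no [0,1] rescaling).
.read_tiff_planes <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  lapply(planes, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop("image format error: multi-sample (color) planes are not supported")
      p <- p[, , 1L]
    }
    p
  })
}

#' Read a multilevel TIFF as a ChannelStack
#'
#' Loads the planes referenced by the panel (by 0-based \code{plane_index}),
#' in panel order, and widens them to double precision with values
#' unchanged. Extra planes in the file (e.g. open blank collection channels)
#' are ignored.
#'
#' @param path Path to a multilevel TIFF (16-bit integer or float planes).
#' @param panel A \linkS4class{Panel}.
#' @param roi_id,batch_id Identifiers stored on the stack.
#' @param pixel_size_um Pixel size; IMC is 1 um/pixel.
#' @return A \linkS4class{ChannelStack} with one plane per panel channel.
#' @export
readImage <- function(path, panel, roi_id = basename(path), batch_id = "1",
                      pixel_size_um = 1.0) {
  stopifnot(is(panel, "Panel"))
  planes <- .read_tiff_planes(path)
  idx <- panel@channels$plane_index
  if (length(planes) < max(idx) + 1L)
    stop("image format error: TIFF has ", length(planes),
         " planes but the panel references plane index ", max(idx))
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("image format error: planes have mismatched shapes")
  H <- dims[1, 1]; W <- dims[2, 1]
  data <- array(0, dim = c(length(idx), H, W))
  for (i in seq_along(idx)) data[i, , ] <- as.numeric(planes[[idx[i] + 1L]])
  dimnames(data) <- list(markerNames(panel), NULL, NULL)
  new("ChannelStack", data = data, pixel_size_um = pixel_size_um,
      roi_id = roi_id, batch_id = batch_id)
}

#' Write a ChannelStack as a 16-bit multilevel TIFF
#'
#' Values must be integers in [0, 65535] (the IMC detector range); they are
#' stored losslessly so that [readImage()] round-trips exactly.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(stack, path) {
  stopifnot(is(stack, "ChannelStack"))
  d <- stack@data
  if (any(d != round(d)) || any(d > 65535))
    stop("writeImage() stores 16-bit integers; values must be whole numbers in [0, 65535]")
  planes <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label mask
#'
#' Reads a single-plane integer image (TIFF or PNG) and relabels the cells
#' to contiguous 1..n_cells, preserving the pixel partition. The original
#' label of each new id is kept in the \code{mapping} slot.
#'
#' @param path Path to a TIFF or PNG label image.
#' @return A \linkS4class{LabelMask}.
#' @export
readMask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- round(img * (2^depth - 1))
  } else {
    planes <- .read_tiff_planes(path)
    if (length(planes) != 1L)
      stop("mask format error: expected a single-plane image")
    m <- planes[[1]]
  }
  if (any(m < 0) || any(m != round(m)))
    stop("mask format error: labels must be non-negative integers")
  .as_label_mask(matrix(as.integer(m), nrow(m), ncol(m)))
}

# Relabel a non-negative integer matrix to contiguous 1..n and wrap it.
.as_label_mask <- function(m) {
  old <- sort(unique(m[m > 0L]))
  lut <- integer(if (length(old)) max(old) else 0L)
  lut[old] <- seq_along(old)
  out <- m
  pos <- m > 0L
  out[pos] <- lut[m[pos]]
  new("LabelMask", labels = out, n_cells = length(old),
      mapping = stats::setNames(old, seq_along(old)))
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  if (mask@n_cells > 65535) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(mask@labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write the minimal neighborhood-analysis CSV
#'
#' Exports exactly the three columns the spatial stage needs: the ROI id,
#' the within-ROI cell id and the final cluster assignment.
#'
#' @param ct A clustered \linkS4class{CellTable} (\code{final_cluster}
#'   populated).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNeighborhoodCSV <- function(ct, path) {
  stopifnot(is(ct, "CellTable"))
  cd <- colData(ct)
  if (!"final_cluster" %in% colnames(cd))
    stop("final_cluster column missing; run mergeClusters() first")
  df <- data.frame(roi_id = cd$roi_id, cell_id = cd$cell_id,
                   final_cluster = as.character(cd$final_cluster))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-ROI cluster composition summary
#'
#' One row per ROI with the total cell count plus, for every final cluster,
#' its cell count (\code{n_<cluster>}) and percentage (\code{pct_<cluster>});
#' percentages sum to 100 within each row.
#'
#' @param ct A clustered \linkS4class{CellTable}.
#' @param path Output CSV path.
#' @return The summary data.frame, invisibly.
#' @export
writeClusterSummary <- function(ct, path) {
  stopifnot(is(ct, "CellTable"))
  cd <- colData(ct)
  if (!"final_cluster" %in% colnames(cd))
    stop("final_cluster column missing; run mergeClusters() first")
  tab <- table(roi = as.character(cd$roi_id),
               cluster = as.character(cd$final_cluster))
  counts <- as.matrix(tab)
  total <- rowSums(counts)
  pct <- sweep(counts, 1, total, "/") * 100
  df <- data.frame(roi_id = rownames(counts), total_cells = as.integer(total),
                   check.names = FALSE)
  for (cl in colnames(counts)) df[[paste0("n_", cl)]] <- counts[, cl]
  for (cl in colnames(counts)) df[[paste0("pct_", cl)]] <- pct[, cl]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
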