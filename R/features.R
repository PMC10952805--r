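#' @include AllClasses.R utils.R
NULL

#' Cap hot and cold pixels
#'
#' Per channel, pixel values below the low percentile are raised to it and
#' values above the high percentile lowered to it, computed over all pixels
#' of the ROI with linear-interpolation percentiles. Rare isolated "hot"
#' pixels are an IMC detector artifact that would otherwise dominate
#' per-cell means. The default (0, 99.9) caps only the extreme tail; (5, 95)
#' reproduces the aggressive top-and-bottom-5% capping used in some IMC
#' workflows.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param low_percentile Percentile in [0, 50).
#' @param high_percentile Percentile in (50, 100].
#' @return A \linkS4class{ChannelStack} of unchanged shape.
#' @export
capHotPixels <- function(stack, low_percentile = 0, high_percentile = 99.9) {
  stopifnot(is(stack, "ChannelStack"))
  if (!is.numeric(low_percentile) || !is.numeric(high_percentile) ||
      low_percentile < 0 || low_percentile >= 50 ||
      high_percentile <= 50 || high_percentile > 100 ||
      low_percentile >= high_percentile)
    stop("invalid percentile bounds: need 0 <= low < 50 < high <= 100")
  d <- stack@data
  for (i in seq_len(dim(d)[1])) {
    v <- d[i, , ]
    lo <- .pctile(v, low_percentile)
    hi <- .pctile(v, high_percentile)
    d[i, , ] <- pmin(pmax(v, lo), hi)
  }
  initialize(stack, data = d)
}

#' Extract per-cell features from an image and its segmentation mask
#'
#' For every labelled cell: the arithmetic mean intensity of each channel
#' over the cell's pixels, the area (pixel count times pixel size squared),
#' the unweighted pixel-coordinate centroid (0-based, origin top-left,
#' x = column, y = row) and an edge flag set when any pixel of the cell lies
#' on the image border.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param mask A \linkS4class{LabelMask} of the same height/width.
#' @param panel Optional \linkS4class{Panel} supplying channel metadata.
#' @return A \linkS4class{CellTable} with assay \code{"raw"}; empty (0
#'   cells) when the mask has no labels.
#' @export
extractFeatures <- function(stack, mask, panel = NULL) {
  stopifnot(is(stack, "ChannelStack"), is(mask, "LabelMask"))
  d <- stack@data
  H <- dim(d)[2]; W <- dim(d)[3]
  if (nrow(mask@labels) != H || ncol(mask@labels) != W)
    stop("shape mismatch between image (", H, "x", W, ") and mask (",
         nrow(mask@labels), "x", ncol(mask@labels), ")")
  C <- dim(d)[1]
  ch_names <- dimnames(d)[[1]]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(C))
  n <- mask@n_cells
  rd <- if (!is.null(panel)) {
    stopifnot(is(panel, "Panel"), nChannels(panel) == C)
    panel@channels
  } else NULL

  if (n == 0L) {
    raw <- matrix(numeric(0), nrow = C, ncol = 0,
                  dimnames = list(ch_names, NULL))
    cd <- DataFrame(roi_id = character(0), batch_id = character(0),
                    cell_id = integer(0), centroid_x = numeric(0),
                    centroid_y = numeric(0), area_um2 = numeric(0),
                    edge_flag = logical(0))
    return(CellTable(raw, cd, channelData = rd))
  }

  idx <- which(mask@labels > 0L)
  lab <- mask@labels[idx]
  counts <- tabulate(lab, nbins = n)
  # 0-based row/col of each foreground pixel (column-major index arithmetic)
  row0 <- (idx - 1L) %% H
  col0 <- (idx - 1L) %/% H
  raw <- matrix(0, nrow = C, ncol = n, dimnames = list(ch_names, NULL))
  for (i in seq_len(C)) {
    plane <- d[i, , ]
    raw[i, ] <- rowsum(plane[idx], lab, reorder = TRUE)[, 1] / counts
  }
  cy <- unname(rowsum(as.numeric(row0), lab, reorder = TRUE)[, 1] / counts)
  cx <- unname(rowsum(as.numeric(col0), lab, reorder = TRUE)[, 1] / counts)
  on_edge <- row0 == 0L | row0 == H - 1L | col0 == 0L | col0 == W - 1L
  edge <- unname(rowsum(as.numeric(on_edge), lab, reorder = TRUE)[, 1] > 0)
  cd <- DataFrame(roi_id = rep(stack@roi_id, n),
                  batch_id = rep(stack@batch_id, n),
                  cell_id = seq_len(n),
                  centroid_x = cx, centroid_y = cy,
                  area_um2 = counts * stack@pixel_size_um^2,
                  edge_flag = edge)
  CellTable(raw, cd, channelData = rd)
}

#' Read a spillover matrix CSV
#'
#' Square matrix with header = channel (marker) names, rows = source
#' channel, columns = receiving channel; diagonal 1, off-diagonal in [0, 1).
#'
#' @param path CSV path.
#' @return A named square matrix.
#' @export
readSpillover <- function(path) {
  if (!file.exists(path)) stop("spillover file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  S <- as.matrix(df)
  .check_spillover(S)
  S
}

.check_spillover <- function(S) {
  if (nrow(S) != ncol(S)) stop("spillover matrix must be square")
  if (any(abs(diag(S) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  off <- S[row(S) != col(S)]
  if (any(off < 0) || any(off >= 1))
    stop("off-diagonal spillover must lie in [0, 1)")
  invisible(TRUE)
}

#' Compensate cell-level intensities for isotope spillover
#'
#' Inverts the linear mixing model m = c S (rows of S = source channel,
#' columns = receiving channel) on the per-cell mean intensities. The
#' default solver is nonnegative least squares (c = argmin_{c >= 0}
#' ||c S - m||_2), matching standard CyTOF compensation practice; the
#' \code{"inverse"} method applies S^-1 and clips at zero. The raw assay is
#' preserved; corrected values are stored in the \code{"compensated"} assay,
#' which downstream transforms pick up as the working intensities.
#'
#' @param ct A \linkS4class{CellTable}.
#' @param S Spillover matrix; its dimnames must match (a subset of) the
#'   channel names of \code{ct}, in order.
#' @param method \code{"nnls"} (default) or \code{"inverse"}.
#' @return The \linkS4class{CellTable} with a \code{"compensated"} assay.
#' @export
compensate <- function(ct, S, method = c("nnls", "inverse")) {
  stopifnot(is(ct, "CellTable"))
  method <- match.arg(method)
  .check_spillover(S)
  chans <- rownames(S)
  if (is.null(chans)) {
    if (nrow(S) != nrow(ct))
      stop("unnamed spillover matrix must cover all ", nrow(ct), " channels")
    chans <- rownames(ct)
  }
  if (!all(chans %in% rownames(ct)))
    stop("spillover channels absent from table: ",
         paste(setdiff(chans, rownames(ct)), collapse = ", "))
  M <- assay(ct, .working_assay(ct))
  out <- M
  m <- t(M[chans, , drop = FALSE])   # cells x K measured
  if (method == "inverse") {
    if (!is.finite(rcond(S)) || rcond(S) < 1e-12)
      stop("spillover matrix is singular; use method = 'nnls'")
    Sinv <- solve(S)
    corrected <- pmax(m %*% Sinv, 0)
  } else {
    A <- t(S)                        # solve min ||A c - m_i||, c >= 0
    corrected <- t(apply(m, 1, function(mi) pracma::lsqnonneg(A, mi)$x))
    if (ncol(S) == 1L) corrected <- matrix(corrected, ncol = 1L)
  }
  out[chans, ] <- t(corrected)
  assay(ct, "compensated") <- out
  ct
}
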