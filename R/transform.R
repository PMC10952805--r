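#' @include AllClasses.R utils.R
NULL

#' Arcsinh transformation
#'
#' The variance-stabilizing transform y = asinh(x / cofactor) used
#' throughout cytometry. The cofactor controls how much of the low-intensity
#' range is linearized; for IMC mean intensities a cofactor of 1 maximizes
#' the separation between negative and positive signal distributions (see
#' [titrateCofactor()]), whereas suspension mass cytometry conventionally
#' uses 5 and fluorescence 100-150.
#'
#' Applied to a \linkS4class{CellTable}, the working intensities
#' (compensated if present, otherwise raw) are transformed into the
#' \code{"transformed"} assay.
#'
#' @param x Numeric values, or a \linkS4class{CellTable}.
#' @param cofactor Positive divisor (default 1, the IMC optimum).
#' @return Transformed values of the same shape, or the updated table.
#' @export
arcsinhTransform <- function(x, cofactor = 1) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0)
    stop("cofactor must be a single positive number")
  if (is(x, "CellTable")) {
    assay(x, "transformed") <- asinh(assay(x, .working_assay(x)) / cofactor)
    metadata(x)$arcsinh_cofactor <- cofactor
    return(x)
  }
  asinh(x / cofactor)
}

#' Robust population statistics: median and rSD
#'
#' The robust standard deviation is defined by percentiles,
#' rSD = (P84.13 - P15.87) / 2 (linear-interpolation percentiles) — the
#' half-width that equals sigma exactly for a normal distribution and is
#' insensitive to the heavy tails of cytometry intensity data.
#'
#' @param values Numeric vector of length >= 2.
#' @return A list with elements \code{median} and \code{rsd}.
#' @export
robustStats <- function(values) {
  if (length(values) < 2L) stop("robustStats() needs at least 2 values")
  list(median = .pctile(values, 50),
       rsd = (.pctile(values, 84.13) - .pctile(values, 15.87)) / 2)
}

#' Fisher discrimination ratio (Rd) between two signal populations
#'
#' Rd = (median_pos - median_neg)^2 / (rSD_pos^2 + rSD_neg^2), the
#' resolution metric scoring how well a positive population separates from
#' a negative one. It is symmetric in group order and invariant under a
#' common affine rescaling of both groups. When both rSDs are zero it is 0
#' for equal medians and +Inf otherwise.
#'
#' @param neg,pos Numeric vectors (>= 2 values each) for the gated negative
#'   and positive populations.
#' @return A non-negative number (possibly \code{Inf}).
#' @seealso [robustStats()], [titrateCofactor()]
#' @export
fisherRd <- function(neg, pos) {
  if (length(neg) < 2L || length(pos) < 2L)
    stop("both groups need at least 2 values")
  sn <- robustStats(neg); sp <- robustStats(pos)
  num <- (sp$median - sn$median)^2
  den <- sp$rsd^2 + sn$rsd^2
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Titrate the arcsinh cofactor against Rd
#'
#' Computes the Fisher discrimination ratio between the arcsinh-transformed
#' negative and positive populations at every cofactor of the grid and
#' reports the maximizer (ties broken toward the smaller cofactor, i.e.
#' stronger compression). The default grid spans the ranges conventionally
#' quoted for fluorescence (100-150) down through suspension mass cytometry
#' (5) to sub-unit values.
#'
#' @param neg,pos Numeric vectors of raw (untransformed) intensities.
#' @param grid Positive cofactors to test.
#' @return An \linkS4class{RdCurve}.
#' @export
titrateCofactor <- function(neg, pos,
                            grid = c(150, 120, 100, 50, 20, 10, 5, 2, 1,
                                     0.5, 0.1)) {
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid <= 0))
    stop("grid must be a non-empty set of positive cofactors")
  rd <- vapply(grid, function(cf)
    fisherRd(asinh(neg / cf), asinh(pos / cf)), numeric(1))
  best <- max(rd)
  optimum <- min(grid[rd == best])
  new("RdCurve", cofactors = as.numeric(grid), rd_values = rd,
      optimum = optimum)
}

#' Z-score normalization of transformed intensities
#'
#' Within each group defined by \code{scope} — \code{"batch"} (default; per
#' \code{batch_id}), \code{"image"} (per \code{roi_id}) or \code{"global"}
#' — each channel of the \code{"transformed"} assay is centered and scaled
#' to unit standard deviation; constant channels map to 0 (their sigma is
#' recorded as 0). Per-batch scope removes multiplicative staining batch
#' effects that a single global affine map cannot touch, and simultaneously
#' puts markers on a common scale for heatmap display. The fitted group
#' means and SDs are recorded in
#' \code{metadata(ct)$normalization}.
#'
#' @param ct A \linkS4class{CellTable} with a \code{"transformed"} assay.
#' @param channels Channel names to normalize (default all).
#' @param scope \code{"batch"}, \code{"image"} or \code{"global"}.
#' @return The table with a \code{"normalized"} assay added.
#' @export
zscoreNormalize <- function(ct, channels = NULL,
                            scope = c("batch", "global", "image")) {
  stopifnot(is(ct, "CellTable"))
  scope <- match.arg(scope)
  if (!"transformed" %in% assayNames(ct))
    stop("run arcsinhTransform() before zscoreNormalize()")
  Y <- assay(ct, "transformed")
  if (is.null(channels)) channels <- rownames(Y)
  if (!all(channels %in% rownames(Y)))
    stop("unknown channels: ",
         paste(setdiff(channels, rownames(Y)), collapse = ", "))
  grp <- switch(scope,
                global = rep("all", ncol(ct)),
                batch = as.character(colData(ct)$batch_id),
                image = as.character(colData(ct)$roi_id))
  Z <- Y
  rec <- list()
  for (g in unique(grp)) {
    j <- grp == g
    for (chn in channels) {
      v <- Y[chn, j]
      mu <- mean(v)
      sg <- stats::sd(v)
      if (!is.finite(sg) || sg == 0) {
        Z[chn, j] <- 0
        sg <- 0
      } else {
        Z[chn, j] <- (v - mu) / sg
      }
      rec[[length(rec) + 1L]] <- data.frame(group = g, channel = chn,
                                            mu = mu, sigma = sg)
    }
  }
  assay(ct, "normalized") <- Z
  metadata(ct)$normalization <- list(scope = scope,
                                     stats = do.call(rbind, rec))
  ct
}

#' 0-1 min-max scaling of transformed intensities
#'
#' The alternative normalization arm: per channel (globally over all
#' cells), y' = clip((y - P_low) / (P_high - P_low), 0, 1). Being a single
#' per-channel affine map it cannot remove between-batch structure, which
#' is exactly why it serves as the negative comparison to per-batch
#' Z-scoring. Results go to the \code{"scaled01"} assay. Channels with a
#' degenerate percentile span map to 0.
#'
#' @param ct A \linkS4class{CellTable} with a \code{"transformed"} assay.
#' @param channels Channel names (default all).
#' @param low_pct,high_pct Percentile anchors (defaults 0 and 100).
#' @return The table with a \code{"scaled01"} assay added.
#' @export
minmaxScale <- function(ct, channels = NULL, low_pct = 0, high_pct = 100) {
  stopifnot(is(ct, "CellTable"))
  if (low_pct >= high_pct) stop("low_pct must be smaller than high_pct")
  if (!"transformed" %in% assayNames(ct))
    stop("run arcsinhTransform() before minmaxScale()")
  Y <- assay(ct, "transformed")
  if (is.null(channels)) channels <- rownames(Y)
  S <- Y
  for (chn in channels) {
    v <- Y[chn, ]
    lo <- .pctile(v, low_pct); hi <- .pctile(v, high_pct)
    S[chn, ] <- if (hi > lo) pmin(pmax((v - lo) / (hi - lo), 0), 1) else 0
  }
  assay(ct, "scaled01") <- S
  ct
}

#' Batch mixing entropy of a cell embedding
#'
#' Quantifies how well batches are mixed in feature space: for every cell,
#' the Shannon entropy of the batch composition among its k Euclidean
#' nearest neighbors, normalized by log(number of batches), averaged over
#' cells. 1 means batches are perfectly interleaved; 0 means each cell's
#' neighborhood is a single batch (complete batch separation).
#'
#' @param matrix Cells x channels numeric matrix.
#' @param batch_labels Batch assignment per cell (>= 2 distinct values).
#' @param k Neighbor count (default 30; must be < number of cells).
#' @return A number in [0, 1].
#' @export
batchMixingEntropy <- function(matrix, batch_labels, k = 30) {
  X <- as.matrix(matrix)
  n <- nrow(X)
  b <- factor(batch_labels)
  if (nlevels(b) < 2L) stop("at least 2 batches are required")
  if (length(b) != n) stop("one batch label per cell required")
  if (k >= n) stop("k must be smaller than the number of cells")
  nb <- nlevels(b)
  bi <- as.integer(b)
  sq <- rowSums(X^2)
  ent <- numeric(n)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    jj <- start:min(start + chunk - 1L, n)
    D <- outer(sq[jj], sq, "+") - 2 * X[jj, , drop = FALSE] %*% t(X)
    for (r in seq_along(jj)) {
      d <- D[r, ]
      d[jj[r]] <- Inf                       # exclude self
      nn <- order(d)[seq_len(k)]
      p <- tabulate(bi[nn], nbins = nb) / k
      p <- p[p > 0]
      ent[jj[r]] <- -sum(p * log(p)) / log(nb)
    }
  }
  mean(ent)
}

#' Quadrant fractions for a bivariate gate
#'
#' Splits cells by two per-channel thresholds (>= threshold counts as
#' positive) and returns the four fractions in the order A-B-, A+B-, A-B+,
#' A+B+. The double-positive fraction of mutually exclusive lineage markers
#' (e.g. CD3 vs CD79a) is the "nonsense cell" screen for segmentation
#' quality: true cells cannot co-express both.
#'
#' @param ct A \linkS4class{CellTable}.
#' @param channel_a,channel_b Channel names.
#' @param thr_a,thr_b Positivity thresholds.
#' @param assay_name Assay to gate on (default \code{"transformed"}).
#' @return Named numeric vector of four fractions summing to 1.
#' @export
quadrantFractions <- function(ct, channel_a, channel_b, thr_a, thr_b,
                              assay_name = "transformed") {
  stopifnot(is(ct, "CellTable"))
  if (!assay_name %in% assayNames(ct)) stop("assay '", assay_name, "' not present")
  Y <- assay(ct, assay_name)
  for (chn in c(channel_a, channel_b))
    if (!chn %in% rownames(Y)) stop("channel '", chn, "' not present")
  a <- Y[channel_a, ] >= thr_a
  b <- Y[channel_b, ] >= thr_b
  n <- length(a)
  if (n == 0L) stop("empty table")
  c("neg_neg" = sum(!a & !b), "a_pos" = sum(a & !b),
    "b_pos" = sum(!a & b), "double_pos" = sum(a & b)) / n
}
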