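#' @include AllClasses.R utils.R
NULL

# FCS 3.1 writer/reader. Single dialect: little-endian ($BYTEORD 1,2,3,4),
# list mode, float32 for every parameter ($DATATYPE F). String metadata is
# encoded as integer codes with a sidecar key CSV, since FCS parameters are
# numeric.

.fcs_sanitize <- function(x, delim = "/") gsub(delim, "-", x, fixed = TRUE)

# Assemble the numeric export matrix (events x parameters) from a CellTable,
# plus the code key for string-valued columns.
.fcs_matrix <- function(ct, include_blank = FALSE) {
  cd <- colData(ct)
  keep <- if (include_blank || !"blank" %in% colnames(rowData(ct)))
    seq_len(nrow(ct)) else which(!rowData(ct)$blank)
  tags <- c(raw = "raw", compensated = "comp", transformed = "asinh",
            normalized = "z")
  cols <- list()
  for (a in intersect(names(tags), assayNames(ct))) {
    m <- assay(ct, a)[keep, , drop = FALSE]
    for (i in seq_len(nrow(m)))
      cols[[paste0(rownames(m)[i], "_", tags[[a]])]] <- m[i, ]
  }
  cols$centroid_x <- cd$centroid_x
  cols$centroid_y <- cd$centroid_y
  cols$area_um2 <- cd$area_um2
  cols$cell_id <- as.numeric(cd$cell_id)
  cols$edge <- as.numeric(cd$edge_flag)
  key <- list()
  code <- function(name, v) {
    f <- factor(as.character(v))
    key[[name]] <<- data.frame(parameter = name,
                               code = seq_along(levels(f)),
                               value = levels(f))
    as.numeric(f)
  }
  cols$batch <- code("batch", cd$batch_id)
  cols$roi <- code("roi", cd$roi_id)
  if ("som_id" %in% colnames(cd)) cols$som_id <- as.numeric(cd$som_id)
  if ("csom_id" %in% colnames(cd)) cols$csom_id <- as.numeric(cd$csom_id)
  if ("final_cluster" %in% colnames(cd))
    cols$final_cluster <- code("final_cluster", cd$final_cluster)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(matrix = X, key = do.call(rbind, key))
}

#' Write a CellTable to an FCS 3.1 file
#'
#' Exports every intensity column of the present assays (raw / compensated /
#' arcsinh-transformed / Z-normalized, suffixed \code{_raw}, \code{_comp},
#' \code{_asinh}, \code{_z}), the x/y centroids, cell area, within-ROI cell
#' id, edge flag, and integer-coded batch/ROI (and final cluster, if
#' present) parameters. Blank channels are excluded by default. String
#' metadata codes are written to a sidecar CSV (\code{<path>.key.csv}) so
#' the mapping back to names is retained. Data are stored as little-endian
#' float32, so a read-back reproduces values to float32 rounding.
#'
#' @param ct A non-empty \linkS4class{CellTable}.
#' @param path Output path for the FCS file.
#' @param include_blank Carry blank channels into the file (default FALSE).
#' @return \code{path}, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(ct, path, include_blank = FALSE) {
  stopifnot(is(ct, "CellTable"))
  if (ncol(ct) == 0L) stop("cannot write an FCS file from an empty table")
  mk <- .fcs_matrix(ct, include_blank = include_blank)
  X <- mk$matrix
  bad <- colnames(X)[!vapply(seq_len(ncol(X)),
                             function(j) all(is.finite(X[, j])), logical(1))]
  if (length(bad))
    stop("non-finite values in column(s): ", paste(bad, collapse = ", "))
  n_par <- ncol(X); n_tot <- nrow(X)
  data_bytes <- 4L * n_par * n_tot

  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (j in seq_len(n_par)) {
    rng <- max(1, ceiling(max(abs(X[, j]), na.rm = TRUE)) + 1)
    kw[[sprintf("$P%dN", j)]] <- .fcs_sanitize(colnames(X)[j])
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- as.character(rng)
  }

  text_start <- 58L
  build_text <- function(db, de) {
    all_kw <- c(kw, "$BEGINDATA" = as.character(db),
                "$ENDDATA" = as.character(de))
    paste0("/", paste0(names(all_kw), "/", unname(all_kw), "/",
                       collapse = ""))
  }
  # $BEGINDATA/$ENDDATA live inside TEXT, whose length depends on their
  # digit count: iterate until the offsets are stable.
  db <- text_start; de <- db + data_bytes - 1L
  for (rep in 1:5) {
    txt <- build_text(db, de)
    db2 <- text_start + nchar(txt, type = "bytes")
    de2 <- db2 + data_bytes - 1L
    if (db2 == db && de2 == de) break
    db <- db2; de <- de2
  }
  txt <- build_text(db, de)
  text_end <- text_start + nchar(txt, type = "bytes") - 1L

  hdr_off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_end),
                   if (de <= 99999999) paste0(hdr_off(db), hdr_off(de))
                   else paste0(hdr_off(0), hdr_off(0)),
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(X)), con, size = 4L, endian = "little")
  if (!is.null(mk$key))
    utils::write.csv(mk$key, paste0(path, ".key.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an FCS file written by this package
#'
#' A minimal FCS 3.0/3.1 reader supporting list mode with a single
#' \code{$DATATYPE F} (float32) or \code{D} (float64) for all parameters —
#' the dialect [writeFCS()] emits. Used to verify round-trips and to re-load
#' exported tables.
#'
#' @param path Path to an FCS file.
#' @return A list with \code{data} (events x parameters matrix, parameter
#'   short names as column names) and \code{keywords} (named character
#'   vector of the TEXT segment).
#' @export
readFCS <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, what = "raw", n = sz)
  header <- rawToChar(raw[1:58])
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(i) as.integer(trimws(substr(header, 11 + 8 * (i - 1), 10 + 8 * i)))
  ts <- off(1); te <- off(2)
  txt <- rawToChar(raw[(ts + 1):(te + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))

  db <- as.numeric(kw[["$BEGINDATA"]]); de <- as.numeric(kw[["$ENDDATA"]])
  if (is.na(db) || db == 0) { db <- off(3); de <- off(4) }
  n_par <- as.integer(kw[["$PAR"]]); n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  size <- switch(dtype, F = 4L, D = 8L,
                 stop("unsupported $DATATYPE: ", dtype))
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  con <- rawConnection(raw[(db + 1):(de + 1)])
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n_par * n_tot, size = size,
               endian = endian)
  X <- matrix(v, nrow = n_tot, ncol = n_par, byrow = TRUE)
  pn <- vapply(seq_len(n_par), function(j) {
    nm <- kw[[sprintf("$P%dN", j)]]
    if (is.null(nm)) sprintf("P%d", j) else nm
  }, character(1))
  colnames(X) <- pn
  list(data = X, keywords = kw)
}
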