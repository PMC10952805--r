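# Shared fixture builders; everything is generated in code.

as_mask <- function(m) imcpipe:::.as_label_mask(matrix(as.integer(m), nrow(m), ncol(m)))

tiny_panel <- function(markers = c("CD3", "CD79a", "DNA"),
                       clustering = rep(TRUE, length(markers)),
                       blank = rep(FALSE, length(markers)),
                       plane_index = seq_along(markers) - 1L) {
  new("Panel", channels = S4Vectors::DataFrame(
    plane_index = as.integer(plane_index),
    metal = paste0("M", seq_along(markers)),
    marker = markers, use_for_clustering = clustering, blank = blank))
}

make_stack <- function(data, roi_id = "roi1", batch_id = "1",
                       pixel_size_um = 1.0) {
  new("ChannelStack", data = data, pixel_size_um = pixel_size_um,
      roi_id = roi_id, batch_id = batch_id)
}

# A directly assembled CellTable with sensible geometry defaults.
make_table <- function(raw, roi_id = "roi1", batch_id = "1",
                       area = 50, edge = FALSE, final_cluster = NULL) {
  raw <- as.matrix(raw)
  n <- ncol(raw)
  cd <- S4Vectors::DataFrame(
    roi_id = rep_len(roi_id, n), batch_id = rep_len(as.character(batch_id), n),
    cell_id = seq_len(n),
    centroid_x = seq_len(n) - 1, centroid_y = rep(0, n),
    area_um2 = rep_len(area, n), edge_flag = rep_len(edge, n))
  if (!is.null(final_cluster)) cd$final_cluster <- rep_len(final_cluster, n)
  CellTable(raw, cd)
}

write_panel_csv <- function(path, n = 28, n_cluster = 27) {
  df <- data.frame(plane_index = seq_len(n) - 1L,
                   metal = sprintf("%dXx", 140 + seq_len(n)),
                   marker = c(sprintf("mkr%02d", seq_len(n - 1)), "DNA"),
                   use_for_clustering = c(rep(TRUE, n_cluster),
                                          rep(FALSE, n - n_cluster)),
                   blank = FALSE)
  write.csv(df, path, row.names = FALSE)
  df
}

# Independent linear-interpolation percentile, written from the definition
# (rank position h = (n-1) p + 1, interpolate adjacent order statistics).
oracle_pctile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
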