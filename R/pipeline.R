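#' @include AllClasses.R io.R features.R transform.R clustering.R spatial.R synthetic.R
#' @importFrom BiocGenerics cbind
NULL

#' Combine per-ROI cell tables
#'
#' Column-binds \linkS4class{CellTable}s sharing the same channels and
#' assays into one table.
#'
#' @param tables List of \linkS4class{CellTable}s.
#' @return A single \linkS4class{CellTable}.
#' @export
combineCellTables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  out <- do.call(cbind, tables)
  as(out, "CellTable")
}

.cfg_get <- function(cfg, field, default = NULL, required = FALSE) {
  v <- cfg[[field]]
  if (is.null(v)) {
    if (required) stop("config field '", field, "' is missing")
    v <- default
  }
  v
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Default simulated experiment: follicle scenes + one marker per cluster.
.simulate_inputs <- function(sim) {
  n_img <- .cfg_get(sim, "n_images", 2L)
  width <- .cfg_get(sim, "width", 200L)
  height <- .cfg_get(sim, "height", 200L)
  n_cells <- .cfg_get(sim, "n_cells", 700L)
  seed <- .cfg_get(sim, "seed", 1L)
  clusters <- c("follicleA", "follicleB", "stroma")
  A <- diag(c(25, 25, 15))
  dimnames(A) <- list(clusters, c("mkrA", "mkrB", "mkrS"))
  A[A == 0] <- 0.4
  stacks <- list(); masks <- list(); rois <- character(n_img)
  batches <- character(n_img)
  for (k in seq_len(n_img)) {
    spec <- tissueSpec(
      width = width, height = height, n_cells = n_cells,
      mean_area_um2 = 0.6 * width * height / n_cells,
      follicles = list(list(center = c(width / 2, height / 2),
                            radius = 0.25 * width,
                            composition = c(follicleA = 0.5, follicleB = 0.5))),
      background_composition = c(stroma = 1), seed = seed + k)
    g <- generateLabelMask(spec)
    ispec <- intensitySpec(A, sigma = 0.2, background = 0.1,
                           gains = 1 + 0.2 * (k %% 2), seed = seed + 100 + k)
    rois[k] <- sprintf("sim_roi%02d", k)
    batches[k] <- as.character((k - 1L) %% 2L + 1L)
    r <- renderChannels(g$mask, g$clusters, ispec, roi_id = rois[k],
                        batch_id = batches[k])
    stacks[[k]] <- r$stack
    masks[[k]] <- g$mask
  }
  panel <- new("Panel", channels = DataFrame(
    plane_index = 0:2, metal = c("M1", "M2", "M3"),
    marker = colnames(A), use_for_clustering = TRUE, blank = FALSE))
  list(stacks = stacks, masks = masks, panel = panel, roi_ids = rois,
       batch_ids = batches)
}

.load_inputs <- function(cfg) {
  panel_path <- .cfg_get(cfg, "panel", required = TRUE)
  images <- .cfg_get(cfg, "images", required = TRUE)
  mask_paths <- .cfg_get(cfg, "masks", required = TRUE)
  panel <- readPanel(panel_path)
  if (length(images) != length(mask_paths))
    stop("config fields 'images' and 'masks' must have equal length")
  rois <- .cfg_get(cfg, "roi_ids", basename(unlist(images)))
  batches <- as.character(.cfg_get(cfg, "batch_ids",
                                   rep("1", length(images))))
  stacks <- mapply(function(p, r, b) readImage(p, panel, roi_id = r,
                                               batch_id = b),
                   images, rois, batches, SIMPLIFY = FALSE)
  masks <- lapply(mask_paths, readMask)
  list(stacks = stacks, masks = masks, panel = panel, roi_ids = rois,
       batch_ids = batches)
}

#' Run the full analysis pipeline
#'
#' Chains the stages — input (or simulation), per-ROI feature extraction
#' with optional hot-pixel capping and spillover compensation, arcsinh
#' transformation, Z-score normalization, SOM + consensus clustering with
#' optional manual merging, spatial neighborhood analysis — and writes the
#' artifact set: \code{cells.csv}, \code{cells.fcs} (+ key sidecar),
#' \code{cluster_heatmap.csv}, \code{cluster_summary.csv},
#' \code{neighborhood.csv}, per-image \code{ternary_<roi>.csv},
#' \code{interactions.csv} and a machine-readable \code{run_log.json}
#' (versions, seeds, parameters). Any stage failure aborts with the stage
#' name and cause. All randomness is funnelled through the seeds recorded
#' in the config, so a rerun reproduces the outputs byte for byte.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   \code{output_dir} (required); either \code{simulate} (list: n_images,
#'   width, height, n_cells, seed) or \code{panel}/\code{images}/
#'   \code{masks} (+ optional \code{roi_ids}, \code{batch_ids},
#'   \code{spillover}, \code{cap = list(low, high)});
#'   \code{transform} (cofactor, zscore_scope); \code{clustering} (rows,
#'   cols, epochs, n_meta, seed, merge CSV path); \code{spatial}
#'   (arguments of [neighborConfig()]).
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- .cfg_get(config, "output_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- .stage("input", {
    if (!is.null(config$simulate)) .simulate_inputs(config$simulate)
    else .load_inputs(config)
  })

  cap <- config$cap
  S <- if (!is.null(config$spillover)) readSpillover(config$spillover)
  ct <- .stage("features", {
    tabs <- lapply(seq_along(inputs$stacks), function(k) {
      st <- inputs$stacks[[k]]
      if (!is.null(cap))
        st <- capHotPixels(st, cap$low, cap$high)
      extractFeatures(st, inputs$masks[[k]], inputs$panel)
    })
    ct <- combineCellTables(tabs)
    if (!is.null(S)) ct <- compensate(ct, S)
    ct
  })

  tr <- config$transform
  ct <- .stage("transform", {
    ct <- arcsinhTransform(ct, cofactor = .cfg_get(tr, "cofactor", 1))
    zscoreNormalize(ct, scope = .cfg_get(tr, "zscore_scope", "batch"))
  })

  cl <- config$clustering
  som_seed <- .cfg_get(cl, "seed", 42L)
  ct <- .stage("clustering", {
    chans <- clusteringChannels(inputs$panel)
    X <- t(normalizedIntensity(ct)[chans, , drop = FALSE])
    model <- trainSOM(X, rows = .cfg_get(cl, "rows", 10),
                      cols = .cfg_get(cl, "cols", 10),
                      epochs = .cfg_get(cl, "epochs", 10), seed = som_seed)
    map <- consensusMetacluster(model, n_meta = .cfg_get(cl, "n_meta", 30))
    ct <- assignMetaclusters(ct, model, map)
    merge <- if (!is.null(cl$merge)) {
      utils::read.csv(cl$merge, colClasses = "character")
    } else {
      ids <- sort(unique(colData(ct)$csom_id))
      data.frame(csom_id = ids, final_cluster = sprintf("C%02d", ids))
    }
    mergeClusters(ct, merge)
  })

  sp_cfg <- do.call(neighborConfig, config$spatial %||% list())
  res <- .stage("spatial", {
    rois <- unique(colData(ct)$roi_id)
    tabs <- lapply(rois, function(r) ct[, colData(ct)$roi_id == r])
    names(tabs) <- rois
    spatialInteractionAnalysis(tabs, inputs$masks[match(rois, inputs$roi_ids)],
                               sp_cfg)
  })

  .stage("export", {
    cd <- as.data.frame(colData(ct))
    mat <- t(assay(ct, "raw"))
    colnames(mat) <- paste0(colnames(mat), "_raw")
    utils::write.csv(cbind(cd, mat), file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    writeFCS(ct, file.path(out_dir, "cells.fcs"))
    hm <- clusterMarkerHeatmap(ct, level = "final",
                               channels = clusteringChannels(inputs$panel))
    utils::write.csv(as.data.frame(hm), file.path(out_dir, "cluster_heatmap.csv"))
    writeClusterSummary(ct, file.path(out_dir, "cluster_summary.csv"))
    writeNeighborhoodCSV(ct, file.path(out_dir, "neighborhood.csv"))
    for (nm in names(res@ternary))
      utils::write.csv(as.data.frame(res@ternary[[nm]]),
                       file.path(out_dir, paste0("ternary_", nm, ".csv")))
    utils::write.csv(as.data.frame(interactionAggregate(res)),
                     file.path(out_dir, "interactions.csv"))
    log <- list(package = "imcpipe",
                version = as.character(utils::packageVersion("imcpipe")),
                r_version = R.version.string,
                seeds = list(clustering = som_seed,
                             spatial = sp_cfg$seed,
                             simulate = config$simulate$seed),
                parameters = list(transform = tr, clustering = cl,
                                  spatial = unclass(sp_cfg)))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
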