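# Small helper: mask from a matrix plus a geometry-only table.
scene_table <- function(mask, clusters, roi_id = "r1") {
  n <- nCells(mask)
  cd <- S4Vectors::DataFrame(
    roi_id = rep(roi_id, n), batch_id = "1", cell_id = seq_len(n),
    centroid_x = rep(0, n), centroid_y = rep(0, n),
    area_um2 = rep(50, n), edge_flag = rep(FALSE, n),
    final_cluster = clusters)
  CellTable(matrix(numeric(0), 0, n), cd)
}

test_that("filterCells applies the area window and edge rule", {
  raw <- matrix(runif(6), 2, 3)
  ct <- make_table(raw, area = c(10, 50, 250))
  kept <- filterCells(ct, neighborConfig())
  expect_equal(nCells(kept), 1)
  expect_equal(cellInfo(kept)$area_um2, 50)
  expect_equal(S4Vectors::metadata(kept)$kept_cell_ids, 2)

  # bounds are inclusive
  ct2 <- make_table(raw, area = c(20, 100, 200))
  expect_equal(nCells(filterCells(ct2)), 3)

  # identity configuration keeps everything in order
  loose <- neighborConfig(min_area_um2 = 0, max_area_um2 = Inf,
                          drop_edge_cells = FALSE)
  expect_identical(cellInfo(filterCells(ct, loose))$cell_id, 1:3)

  # all border cells with edge removal: empty table
  ct3 <- make_table(raw, area = 50, edge = TRUE)
  expect_equal(nCells(filterCells(ct3)), 0)

  # idempotence
  expect_equal(nCells(filterCells(filterCells(ct))), 1)
})

test_that("disc neighbor detection follows pixel-set distance geometry", {
  # two touching 4-connected cells are mutual neighbors at d = 1
  m <- matrix(0L, 5, 6)
  m[2:4, 2] <- 1L; m[2:4, 3] <- 2L
  adj <- findNeighbors(as_mask(m), neighborConfig(distance_px = 1))
  expect_equal(adj@neighbors[[1]], 2L)
  expect_equal(adj@neighbors[[2]], 1L)

  # two 5x5 squares with facing pixel columns 3 apart:
  # not neighbors at d = 2, neighbors at d = 3
  m2 <- matrix(0L, 12, 16)
  m2[3:7, 2:6] <- 1L
  m2[3:7, 9:13] <- 2L   # column gap: |9 - 6| = 3
  d2 <- findNeighbors(as_mask(m2), neighborConfig(distance_px = 2))
  d3 <- findNeighbors(as_mask(m2), neighborConfig(distance_px = 3))
  expect_length(d2@neighbors[[1]], 0)
  expect_equal(d3@neighbors[[1]], 2L)
  expect_equal(d3@neighbors[[2]], 1L)

  # empty mask gives an empty map
  e <- findNeighbors(as_mask(matrix(0L, 4, 4)), neighborConfig())
  expect_equal(e@n_cells, 0)
})

test_that("disc adjacency is symmetric, nested in d, and contained in bbox", {
  set.seed(17)
  for (rep in 1:10) {
    sim <- generateLabelMask(tissueSpec(width = 100, height = 100,
                                        n_cells = 130, mean_area_um2 = 45,
                                        seed = 200 + rep))
    mask <- sim$mask
    prev <- NULL
    for (d in c(3, 5, 10)) {
      disc <- findNeighbors(mask, neighborConfig(distance_px = d))
      bbox <- findNeighbors(mask, neighborConfig(distance_px = d,
                                                 method = "bbox"))
      for (i in seq_len(nCells(mask))) {
        # disc subset of bbox at equal d
        expect_true(all(disc@neighbors[[i]] %in% bbox@neighbors[[i]]))
        # symmetry of disc adjacency
        for (j in disc@neighbors[[i]])
          expect_true(i %in% disc@neighbors[[j]])
        # nestedness in d
        if (!is.null(prev))
          expect_true(all(prev@neighbors[[i]] %in% disc@neighbors[[i]]))
      }
      expect_lte(medianNN(disc), medianNN(bbox))
      if (!is.null(prev)) expect_lte(medianNN(prev), medianNN(disc))
      prev <- disc
    }
  }
})

test_that("medianNN counts neighbors exhaustively", {
  # chain of 5 horizontal cells touching in a row
  m <- matrix(0L, 4, 11)
  for (k in 1:5) m[2:3, (2 * k - 1):(2 * k)] <- k
  adj <- findNeighbors(as_mask(m), neighborConfig(distance_px = 1))
  expect_equal(lengths(adj@neighbors), c(1, 2, 2, 2, 1))
  expect_equal(medianNN(adj), 2)

  # isolated cells have zero neighbors
  iso <- matrix(0L, 9, 9); iso[2, 2] <- 1L; iso[8, 8] <- 2L
  expect_equal(medianNN(findNeighbors(as_mask(iso), neighborConfig())), 0)
  expect_error(medianNN(findNeighbors(as_mask(matrix(0L, 3, 3)),
                                      neighborConfig())), "empty")
})

test_that("permutation test flags constructed interaction and avoidance", {
  # permutation-invariant statistic: single cluster is always 0
  sim1 <- generateLabelMask(tissueSpec(width = 60, height = 60, n_cells = 50,
                                       mean_area_um2 = 45, seed = 4))
  adj1 <- findNeighbors(sim1$mask, neighborConfig())
  r1 <- neighborhoodPermutationTest(rep("A", nCells(sim1$mask)), adj1,
                                    neighborConfig(seed = 2))
  expect_equal(unname(r1$ternary["A", "A"]), 0L)

  # interleaved rare A-B pairs among filler C -> +1; halves -> -1
  sc_int <- simulateInteractionScene("interaction", seed = 21)
  adj_i <- findNeighbors(sc_int$mask, neighborConfig())
  ri <- neighborhoodPermutationTest(sc_int$clusters, adj_i,
                                    neighborConfig(seed = 31))
  expect_equal(unname(ri$ternary["A", "B"]), 1L)
  expect_equal(unname(ri$ternary["B", "A"]), 1L)

  sc_av <- simulateInteractionScene("avoidance", seed = 22)
  adj_a <- findNeighbors(sc_av$mask, neighborConfig())
  ra <- neighborhoodPermutationTest(sc_av$clusters, adj_a,
                                    neighborConfig(seed = 32))
  expect_equal(unname(ra$ternary["A", "C"]), -1L)
  expect_equal(unname(ra$ternary["C", "A"]), -1L)

  # determinism given the seed
  ri2 <- neighborhoodPermutationTest(sc_int$clusters, adj_i,
                                     neighborConfig(seed = 31))
  expect_identical(ri$ternary, ri2$ternary)

  expect_error(neighborhoodPermutationTest(c("A", "B"), adj_i,
                                           neighborConfig()), "cover")
})

test_that("type-I error of the permutation test is controlled under random labels", {
  set.seed(55)
  flags_pos <- 0; flags_neg <- 0; n_pairs <- 0
  for (img in 1:20) {
    sim <- generateLabelMask(tissueSpec(width = 120, height = 120,
                                        n_cells = 260, mean_area_um2 = 45,
                                        seed = 500 + img))
    labs <- sample(c("A", "B", "C"), nCells(sim$mask), replace = TRUE)
    adj <- findNeighbors(sim$mask, neighborConfig())
    r <- neighborhoodPermutationTest(labs, adj,
                                     neighborConfig(seed = 600 + img))
    flags_pos <- flags_pos + sum(r$ternary == 1L)
    flags_neg <- flags_neg + sum(r$ternary == -1L)
    n_pairs <- n_pairs + length(r$ternary)
  }
  bound <- 0.10 + 3 * sqrt(0.10 * 0.90 / 100)
  expect_lte(flags_pos / n_pairs, bound)
  expect_lte(flags_neg / n_pairs, bound)
})

test_that("occupancy filter retains clusters strictly above the threshold", {
  expect_setequal(occupancyFilter(c(A = 0.5, B = 0.05), threshold = 0.1), "A")
  expect_setequal(occupancyFilter(c(A = 0.2, B = 0.7), threshold = 0),
                  c("A", "B"))
  expect_setequal(occupancyFilter(c(A = 1), threshold = 0.01), "A")
  expect_error(occupancyFilter(c(A = 1.2)), "\\[0, 1\\]")
})

test_that("aggregation averages ternaries over images where pairs are defined", {
  t1 <- matrix(1L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- t1; t2[] <- 0L
  t3 <- t1; t3[] <- -1L
  res <- aggregateInteractions(list(t1, t2, t3))
  expect_equal(unname(interactionAggregate(res)["A", "B"]), 0)

  # all-positive pair aggregates to exactly 1
  res2 <- aggregateInteractions(list(t1, t1, t1))
  expect_equal(unname(interactionAggregate(res2)["A", "B"]), 1)

  # pair defined in a subset of images only
  t4 <- matrix(1L, 1, 1, dimnames = list("A", "A"))
  res3 <- aggregateInteractions(list(t1, t4))
  expect_equal(unname(interactionAggregate(res3)["A", "B"]), 1)   # 1 image
  # pair defined in no image is absent (NA)
  res4 <- aggregateInteractions(list(t4), clusters = c("A", "B"))
  expect_true(is.na(interactionAggregate(res4)["A", "B"]))
  expect_error(aggregateInteractions(list()), "at least one")
})

test_that("full spatial analysis on simulated follicles hits the extremes", {
  tabs <- list(); masks <- list()
  for (k in 1:3) {
    sc <- simulateInteractionScene("interaction", seed = 40 + k)
    tabs[[k]] <- syntheticCellTable(sc, roi_id = paste0("r", k))
    masks[[k]] <- sc$mask
  }
  names(tabs) <- paste0("r", 1:3)
  res <- spatialInteractionAnalysis(tabs, masks, neighborConfig(seed = 70))
  expect_equal(unname(interactionAggregate(res)["A", "B"]), 1)
  # determinism of the whole analysis
  res2 <- spatialInteractionAnalysis(tabs, masks, neighborConfig(seed = 70))
  expect_identical(interactionAggregate(res), interactionAggregate(res2))
})
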