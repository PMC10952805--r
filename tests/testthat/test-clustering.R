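# 6 well-separated archetype profiles with small within-type noise.
archetype_sim <- function(n_per = 150, sigma = 0.05, seed = 101) {
  set.seed(seed)
  centers <- diag(6)          # one-hot profiles at unit separation
  X <- do.call(rbind, lapply(1:6, function(k)
    matrix(rnorm(n_per * 6, centers[k, ], sigma), n_per, 6, byrow = TRUE)))
  list(X = X, truth = rep(1:6, each = n_per))
}

test_that("SOM training is deterministic, assigns to nearest node, handles degenerate input", {
  # matrix of one repeated row: everything lands in one node with zero error
  X0 <- matrix(2, 50, 3)
  m0 <- trainSOM(X0, rows = 3, cols = 3, epochs = 2, seed = 5)
  expect_length(unique(m0@assignments), 1)
  expect_equal(m0@quant_error, 0)

  sim <- archetype_sim()
  m1 <- trainSOM(sim$X, seed = 42)
  m2 <- trainSOM(sim$X, seed = 42)
  expect_identical(m1@codebook, m2@codebook)
  expect_identical(m1@assignments, m2@assignments)
  m3 <- trainSOM(sim$X, seed = 43)
  expect_false(identical(m1@assignments, m3@assignments))

  # default grid is 10 x 10 = 100 nodes
  expect_equal(nrow(m1@codebook), 100)

  # nearest-codebook property of the final assignment
  d2 <- as.matrix(dist(rbind(sim$X, m1@codebook)))
  d2 <- d2[seq_len(nrow(sim$X)), nrow(sim$X) + seq_len(100)]
  expect_equal(m1@assignments, apply(d2, 1, which.min), ignore_attr = TRUE)

  # archetype purity: nodes are >99% pure for their archetype
  purity <- vapply(split(sim$truth, m1@assignments), function(tr)
    max(table(tr)) / length(tr), numeric(1))
  expect_gt(min(purity), 0.99)

  expect_error(trainSOM(matrix(1, 1, 3)), "2 cells")
})

test_that("consensus metaclustering recovers separated codebook groups", {
  sim <- archetype_sim()
  model <- trainSOM(sim$X, seed = 42)

  # n_meta = number of nodes is the identity mapping (small fully-occupied grid)
  small <- trainSOM(sim$X, rows = 2, cols = 2, seed = 42)
  ident <- consensusMetacluster(small, n_meta = 4)
  expect_identical(ident@mapping, 1:4)
  # n_meta = 1 merges everything
  one <- consensusMetacluster(small, n_meta = 1)
  expect_identical(unique(one@mapping), 1L)

  # 3 codebook clusters at mutual distance >> diameter
  fake <- model
  set.seed(8)
  groups <- rep(1:3, length.out = 100)
  fake@codebook <- matrix(rnorm(600, sd = 0.01), 100, 6) + 50 * groups
  map3 <- consensusMetacluster(fake, n_meta = 3)
  expect_equal(length(unique(map3@mapping)), 3)
  expect_true(all(vapply(split(map3@mapping, groups),
                         function(v) length(unique(v)) == 1L, logical(1))))

  expect_error(consensusMetacluster(model, n_meta = 0), "at least 1")
  expect_error(consensusMetacluster(model, n_meta = 1e4), "non-empty")
})

test_that("metacluster assignment conserves cells and validates the map", {
  sim <- archetype_sim(n_per = 40)
  model <- trainSOM(sim$X, rows = 4, cols = 4, seed = 9)
  map <- consensusMetacluster(model, n_meta = 6)
  raw <- t(sim$X) + 2   # shift to the non-negative raw-intensity scale
  rownames(raw) <- paste0("ch", 1:6)
  ct <- make_table(raw)
  ct <- assignMetaclusters(ct, model, map)
  cd <- cellInfo(ct)
  expect_equal(length(cd$csom_id), nCells(ct))
  expect_false(anyNA(cd$csom_id))
  expect_identical(cd$csom_id, map@mapping[cd$som_id])

  # identity map: csom equals som
  ident <- new("MetaclusterMap", mapping = 1:16, n_meta = 16L,
               linkage = "average")
  cti <- assignMetaclusters(ct, model, ident)
  expect_identical(cellInfo(cti)$csom_id, cellInfo(cti)$som_id)

  # truncated map triggers the unmapped-node error
  bad <- map; bad@mapping <- map@mapping[seq_len(max(model@assignments) - 1L)]
  expect_error(assignMetaclusters(ct, model, bad), "unmapped")
})

test_that("cluster heatmaps compute medians with the requested normalization", {
  raw <- matrix(c(1, 10, 3, 10, 5, 20, 7, 20), nrow = 2,
                dimnames = list(c("m1", "m2"), NULL))
  ct <- make_table(raw)
  SummarizedExperiment::assay(ct, "transformed") <- raw
  SummarizedExperiment::assay(ct, "normalized") <- raw
  SummarizedExperiment::colData(ct)$csom_id <- c(1L, 1L, 2L, 2L)
  H <- clusterMarkerHeatmap(ct, level = "csom", normalize = "none")
  expect_equal(H["m1", "1"], median(c(1, 3)))
  expect_equal(H["m2", "2"], median(c(20, 20)))
  expect_equal(attr(H, "frequencies"), c("1" = 0.5, "2" = 0.5))

  Hc <- clusterMarkerHeatmap(ct, level = "csom", normalize = "column")
  expect_true(all(apply(Hc, 2, max) == 1))
  expect_true(all(apply(Hc, 2, min) == 0))

  # single cluster: raw medians per channel
  ct1 <- ct
  SummarizedExperiment::colData(ct1)$csom_id <- rep(1L, 4)
  H1 <- clusterMarkerHeatmap(ct1, level = "csom", normalize = "none")
  expect_equal(unname(H1[, 1]), c(median(raw[1, ]), median(raw[2, ])))
})

test_that("manual cluster merging maps every consensus id and pools counts", {
  raw <- matrix(runif(12), 2, 6, dimnames = list(c("x", "y"), NULL))
  ct <- make_table(raw)
  SummarizedExperiment::colData(ct)$csom_id <- c(1L, 1L, 2L, 2L, 2L, 3L)
  out <- mergeClusters(ct, c("1" = "A", "2" = "A", "3" = "B"))
  expect_equal(sum(clusterLabels(out, "final") == "A"), 5)
  expect_equal(sum(clusterLabels(out, "final") == "B"), 1)

  # identity merge preserves the number of clusters
  idm <- setNames(as.character(1:3), 1:3)
  expect_equal(length(unique(clusterLabels(mergeClusters(ct, idm), "final"))), 3)

  expect_error(mergeClusters(ct, c("1" = "A", "2" = "A")), "3")
})

test_that("cluster recovery score behaves like the adjusted Rand index", {
  set.seed(13)
  truth <- sample(1:4, 300, TRUE)
  expect_equal(clusterRecoveryScore(truth, truth), 1)
  # invariant to label renaming
  renamed <- c("d", "c", "b", "a")[truth]
  expect_equal(clusterRecoveryScore(renamed, truth), 1)
  # one big cluster is at chance level
  expect_lt(abs(clusterRecoveryScore(rep(1, 300), truth)), 0.05)
  # independently computed from the contingency-table formula
  pred <- sample(1:3, 300, TRUE)
  ari_oracle <- function(a, b) {
    tab <- table(a, b)
    ch2 <- function(x) x * (x - 1) / 2
    sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab)))
    sj <- sum(ch2(colSums(tab))); stot <- ch2(sum(tab))
    exp_ij <- si * sj / stot
    (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
  }
  expect_equal(clusterRecoveryScore(pred, truth), ari_oracle(pred, truth),
               tolerance = 1e-12)
  expect_error(clusterRecoveryScore(1:5, 1:6), "equal length")
})
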