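test_that("arcsinh transform matches the closed form and validates its cofactor", {
  expect_equal(arcsinhTransform(0, 5), 0)
  expect_equal(arcsinhTransform(8, 1), log(8 + sqrt(65)))
  x <- c(0.1, 1, 10, 100)
  expect_equal(arcsinhTransform(x, 5), asinh(x / 5))
  expect_true(all(diff(arcsinhTransform(sort(x), 2)) > 0))
  expect_error(arcsinhTransform(1, 0), "positive")
  expect_error(arcsinhTransform(1, -3), "positive")
})

test_that("robustStats follows the percentile definition of median and rSD", {
  s <- robustStats(c(0, 1, 2, 3, 4))
  expect_equal(s$median, 2)
  expect_equal(s$rsd, 1.3652, tolerance = 1e-12)   # (3.3652 - 0.6348) / 2

  # cross-check against an independently written percentile interpolation
  set.seed(9)
  v <- rexp(501, 1 / 7)
  s2 <- robustStats(v)
  expect_equal(s2$median, oracle_pctile(v, 50), tolerance = 1e-12)
  expect_equal(s2$rsd,
               (oracle_pctile(v, 84.13) - oracle_pctile(v, 15.87)) / 2,
               tolerance = 1e-12)

  # rSD converges to sigma for a normal sample
  set.seed(10)
  z <- rnorm(200000)
  expect_equal(robustStats(z)$rsd, 1, tolerance = 0.02)

  expect_equal(robustStats(rep(3, 10))$rsd, 0)
  expect_error(robustStats(1), "at least 2")
})

test_that("fisherRd is symmetric, affine-invariant and matches a duplicate implementation", {
  set.seed(12)
  neg <- rexp(5000, 1 / 0.3)
  pos <- rlnorm(5000, log(8), 0.5)
  expect_equal(fisherRd(neg, pos), fisherRd(pos, neg))

  # identical distributions give (near) zero
  expect_lt(fisherRd(neg, neg), 1e-12)

  # affine invariance
  rd0 <- fisherRd(neg, pos)
  expect_equal(fisherRd(3.7 * neg - 2, 3.7 * pos - 2), rd0, tolerance = 1e-12)

  # duplicate implementation from the definition, via the oracle percentiles
  rd_oracle <- function(a, b) {
    rsd <- function(x) (oracle_pctile(x, 84.13) - oracle_pctile(x, 15.87)) / 2
    (oracle_pctile(b, 50) - oracle_pctile(a, 50))^2 / (rsd(a)^2 + rsd(b)^2)
  }
  for (cf in c(100, 1, 0.1)) {
    expect_equal(fisherRd(asinh(neg / cf), asinh(pos / cf)),
                 rd_oracle(asinh(neg / cf), asinh(pos / cf)),
                 tolerance = 1e-12)
  }

  # degenerate rSDs
  expect_equal(fisherRd(c(1, 1), c(1, 1)), 0)
  expect_identical(fisherRd(c(1, 1), c(2, 2)), Inf)
  expect_error(fisherRd(numeric(0), pos), "at least 2")
})

test_that("cofactor titration finds 1 on IMC-scale bimodal data", {
  bm <- generateBimodalChannel(5000, 5000, seed = 42)
  neg <- bm$value[bm$population == "neg"]
  pos <- bm$value[bm$population == "pos"]
  curve <- titrateCofactor(neg, pos, grid = c(100, 1, 0.1))
  expect_equal(rdOptimum(curve), 1)
  rd <- setNames(curve@rd_values, curve@cofactors)
  # near-linear limit (large cofactor) loses resolution
  expect_lt(rd[["100"]], rd[["1"]])

  # grid order does not change the optimum
  curve2 <- titrateCofactor(neg, pos, grid = c(0.1, 100, 1))
  expect_equal(rdOptimum(curve2), 1)
  # single-value grid returns that value
  expect_equal(rdOptimum(titrateCofactor(neg, pos, grid = 7)), 7)
  # arcsinh at huge cofactor converges to the raw-space Rd
  expect_equal(fisherRd(asinh(neg / 1e6), asinh(pos / 1e6)),
               fisherRd(neg, pos), tolerance = 1e-3)
  expect_error(titrateCofactor(neg, pos, grid = numeric(0)), "positive")
  expect_error(titrateCofactor(neg, pos, grid = c(1, -1)), "positive")
})

# Shared 3-batch gain simulation: same biology, per-batch multiplicative gain.
batch_sim <- function(n = 2000, gains = c(0.5, 1, 2), seed = 77) {
  set.seed(seed)
  # two positive markers at IMC-like scale (well above the cofactor, where
  # a multiplicative gain becomes an additive shift after arcsinh)
  base <- cbind(rlnorm(3 * n, log(8), 0.5),
                rlnorm(3 * n, log(15), 0.7))
  batch <- rep(seq_along(gains), each = n)
  raw <- t(base * gains[batch])
  rownames(raw) <- c("chA", "chB")
  make_table(raw, batch_id = batch)
}

test_that("per-batch Z-score removes the simulated batch effect", {
  ct <- batch_sim()
  ct <- arcsinhTransform(ct, 1)
  ct <- zscoreNormalize(ct, scope = "batch")
  Z <- normalizedIntensity(ct)
  b <- cellInfo(ct)$batch_id
  for (g in unique(b)) {
    for (ch in rownames(Z)) {
      expect_lt(abs(mean(Z[ch, b == g])), 1e-10)
      expect_lt(abs(sd(Z[ch, b == g]) - 1), 1e-10)
    }
  }
  # cross-batch distributions align: KS statistic below 0.05
  for (ch in rownames(Z)) {
    ks12 <- suppressWarnings(ks.test(Z[ch, b == "1"], Z[ch, b == "2"]))
    ks13 <- suppressWarnings(ks.test(Z[ch, b == "1"], Z[ch, b == "3"]))
    expect_lt(ks12$statistic, 0.05)
    expect_lt(ks13$statistic, 0.05)
  }
  # the 0-1 scaling arm does not achieve the KS bound
  ct01 <- minmaxScale(arcsinhTransform(batch_sim(), 1))
  S01 <- SummarizedExperiment::assay(ct01, "scaled01")
  expect_true(all(S01 >= 0 & S01 <= 1))
  ks01 <- suppressWarnings(ks.test(S01["chA", b == "1"], S01["chA", b == "3"]))
  expect_gt(ks01$statistic, 0.05)

  # scope recorded; constant channel maps to zero with sigma 0
  expect_equal(S4Vectors::metadata(ct)$normalization$scope, "batch")
  ct2 <- make_table(matrix(4, 1, 10, dimnames = list("const", NULL)))
  ct2 <- zscoreNormalize(arcsinhTransform(ct2), scope = "global")
  expect_true(all(normalizedIntensity(ct2) == 0))
  st <- S4Vectors::metadata(ct2)$normalization$stats
  expect_equal(st$sigma[st$channel == "const"], 0)
})

test_that("minmax scaling follows its closed form", {
  ct <- make_table(matrix(0:10, 1, 11, dimnames = list("m", NULL)))
  ct <- arcsinhTransform(ct, 1e9)   # near-identity transform for the check
  Y <- transformedIntensity(ct)
  ct <- minmaxScale(ct)
  S <- SummarizedExperiment::assay(ct, "scaled01")
  expect_equal(S["m", ], Y["m", ] / Y["m", 11], tolerance = 1e-12)
  # degenerate span maps to zero
  ctc <- minmaxScale(arcsinhTransform(
    make_table(matrix(2, 1, 5, dimnames = list("m", NULL)))))
  expect_true(all(SummarizedExperiment::assay(ctc, "scaled01") == 0))
  expect_error(minmaxScale(ct, low_pct = 90, high_pct = 10), "smaller")
})

test_that("batch mixing entropy separates mixed from split embeddings", {
  set.seed(31)
  # disjoint half-spaces: entropy ~ 0
  X <- rbind(cbind(rnorm(300, 0, .2), rnorm(300, 0, .2)),
             cbind(rnorm(300, 12, .2), rnorm(300, 0, .2)))
  b <- rep(1:2, each = 300)
  expect_lt(batchMixingEntropy(X, b, k = 30), 0.05)

  # random labels on one distribution: entropy ~ 1
  X2 <- matrix(rnorm(2000 * 2), ncol = 2)
  b2 <- sample(1:2, 2000, TRUE)
  expect_gte(batchMixingEntropy(X2, b2, k = 30), 0.95)

  # invariance under a common affine map
  e1 <- batchMixingEntropy(X, b, k = 15)
  expect_equal(batchMixingEntropy(2.5 * X + 7, b, k = 15), e1)

  # the z-scored arm mixes batches better than arcsinh alone
  ct <- batch_sim(n = 700)
  ct <- zscoreNormalize(arcsinhTransform(ct, 1), scope = "batch")
  bb <- cellInfo(ct)$batch_id
  e_raw <- batchMixingEntropy(t(transformedIntensity(ct)), bb, k = 30)
  e_z <- batchMixingEntropy(t(normalizedIntensity(ct)), bb, k = 30)
  expect_gt(e_z, e_raw)

  expect_error(batchMixingEntropy(X, rep(1, nrow(X)), 10), "2 batches")
  expect_error(batchMixingEntropy(X2, b2, k = 2000), "smaller")
})

test_that("quadrant fractions partition the cells", {
  raw <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), nrow = 2,
                dimnames = list(c("CD3", "CD79a"), NULL))
  ct <- arcsinhTransform(make_table(raw), 1)
  q <- quadrantFractions(ct, "CD3", "CD79a", thr_a = 1, thr_b = 1)
  expect_equal(unname(q), rep(0.25, 4))
  expect_equal(sum(q), 1)
  set.seed(3)
  ct2 <- arcsinhTransform(make_table(
    matrix(rexp(400), 2, 200, dimnames = list(c("CD3", "CD79a"), NULL))))
  expect_equal(sum(quadrantFractions(ct2, "CD3", "CD79a", .5, .7)), 1)
  expect_error(quadrantFractions(ct, "CD3", "CD8", 1, 1), "CD8")
})
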