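test_that("pairwise differences match a brute-force pair enumeration", {
  # the fixed worked example
  f <- pairwiseZDifferences(matrix(c(5, 4, 3, 2, 1, 0), nrow = 1))
  expect_identical(ncol(featureValues(f)), 15L)
  expect_equal(as.numeric(featureValues(f)),
               c(1, 2, 3, 4, 5, 1, 2, 3, 4, 1, 2, 3, 1, 2, 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(featureValues(f)),
               bruteForcePairDiffs(c(5, 4, 3, 2, 1, 0)), tolerance = 1e-12)

  # identity case and random rows against the oracle
  expect_equal(as.numeric(featureValues(
    pairwiseZDifferences(matrix(0, 1, 6)))), rep(0, 15))
  set.seed(31)
  for (r in 1:20) {
    zrow <- rnorm(6, sd = 5)
    expect_equal(as.numeric(featureValues(
      pairwiseZDifferences(matrix(zrow, nrow = 1)))),
      bruteForcePairDiffs(zrow), tolerance = 1e-12)
  }
  expect_error(pairwiseZDifferences(matrix(0, 2, 5)), "6 hotspot")
})

test_that("swapping two hotspots negates their pair column", {
  set.seed(8)
  z <- matrix(rnorm(60), ncol = 6)
  pairs <- hotspotPairs(asMatrix = TRUE)
  for (p in seq_len(15)) {
    zSwap <- z
    zSwap[, pairs[p, ]] <- z[, rev(pairs[p, ])]
    a <- featureValues(pairwiseZDifferences(z))
    b <- featureValues(pairwiseZDifferences(zSwap))
    expect_equal(unname(b[, p]), unname(-a[, p]), tolerance = 1e-12)
  }
})

test_that("per-subject body-size offsets cancel in the features", {
  set.seed(12)
  z <- matrix(rnorm(120, 6, 2), ncol = 6)
  for (offset in c(-3.7, 0.4, 12)) {
    fa <- featureValues(pairwiseZDifferences(z))
    fb <- featureValues(pairwiseZDifferences(z + offset))
    expect_equal(fa, fb, tolerance = 1e-12)
  }
})

test_that("concatSessions stacks sessions in order with frame origins", {
  s1 <- makeSession(matrix(rnorm(600), ncol = 6), label = "s01")
  s2 <- makeSession(matrix(rnorm(300), ncol = 6), label = "s02")
  tl <- concatSessions(list(s1, s2))
  expect_identical(nrow(tl@z), 150L)
  expect_identical(tl@origin$session_label,
                   rep(c("s01", "s02"), c(100, 50)))
  expect_identical(tl@origin$frame, c(1:100, 1:50))

  solo <- concatSessions(list(s1))
  expect_identical(solo@z, zMatrix(s1))

  other <- makeSession(matrix(rnorm(60), ncol = 6), id = "zz")
  expect_error(concatSessions(list(s1, other)), "different subjects")
})

test_that("elbow k-means handles degenerate inputs", {
  same <- matrix(5, nrow = 40, ncol = 15)
  fit <- suppressMessages(elbowKmeans(same, clusteringConfig(seed = 1)))
  expect_identical(fit$k, 1L)
  expect_equal(fit$wcss[1], 0)
  expect_true(all(fit$labels == 1L))

  single <- matrix(rnorm(15), nrow = 1)
  fit1 <- suppressMessages(elbowKmeans(single, clusteringConfig(seed = 1)))
  expect_identical(fit1$k, 1L)
  expect_identical(fit1$labels, 1L)

  allNA <- matrix(NA_real_, 3, 15)
  expect_error(elbowKmeans(allNA, clusteringConfig(seed = 1)),
               "no non-missing")
})

test_that("elbow k-means recovers well-separated planted clusters", {
  centers <- matrix(c(0, 0, 100, 0, 0, 100), ncol = 2, byrow = TRUE)
  pl <- plantedClusters(centers, nPer = 100, sd = 1, seed = 90)
  fit <- elbowKmeans(pl$x, clusteringConfig(kMax = 10, seed = 2))
  expect_identical(fit$k, 3L)
  expect_equal(ari(fit$labels, pl$labels), 1)
})

test_that("elbow labels attain the exact minimum-WCSS partition on tiny instances", {
  centers <- matrix(c(0, 0, 8, 0, 4, 7), ncol = 2, byrow = TRUE)
  pl <- plantedClusters(centers, nPer = 4, sd = 0.6, seed = 33)  # 12 points
  oracle <- enumerateMinWCSS(pl$x, 3)
  fit <- withr::with_seed(6,
    PostureSeg:::kmeansFit(pl$x, 3, replicates = 20, maxIter = 300))
  expect_equal(fit$wcss, oracle$wcss, tolerance = 1e-9)
  expect_equal(ari(fit$labels, oracle$labels), 1)
})

test_that("WCSS is non-increasing in k and explained variance is bounded", {
  set.seed(55)
  x <- matrix(rnorm(200 * 15), ncol = 15)
  fit <- elbowKmeans(x, clusteringConfig(kMax = 8, seed = 3))
  expect_true(all(diff(fit$wcss) <= 1e-9 * fit$wcss[1]))
  expect_true(all(fit$explained >= 0 & fit$explained <= 1))
  expect_equal(fit$explained[1], 0)
})

test_that("the engine agrees with a reference k-means on easy data", {
  centers <- matrix(rnorm(5 * 15, sd = 40), ncol = 15)
  pl <- plantedClusters(centers, nPer = 30, sd = 1, seed = 14)
  ours <- withr::with_seed(7,
    PostureSeg:::kmeansFit(pl$x, 5, replicates = 10, maxIter = 300))
  ref <- withr::with_seed(7,
    stats::kmeans(pl$x, centers = 5, nstart = 10, iter.max = 300))
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(ari(ours$labels, ref$cluster), 1)
})

test_that("extractPostures recovers planted archetypes and writes coherent outputs", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(sessionsPerSubject = 2, framesPerSession = 700,
                          seed = 21)
  sim <- simulateSubject(arch, cfg, "156", seed = 21)
  out <- tempfile("subj")
  md <- tempfile("meandist")
  fit <- extractPostures(sim$sessions, clusteringConfig(seed = 5),
                         outDir = out, meanDistDir = md)

  truth <- unlist(sim$truth)
  labels <- unlist(postureLabels(fit), use.names = FALSE)
  keep <- labels > 0
  expect_identical(fit@k, length(unique(truth)))
  expect_gte(ari(labels[keep], truth[keep]), 0.95)

  # posture ids ordered by descending frame count
  expect_true(all(diff(postureCounts(fit)) <= 0))
  expect_identical(sum(postureCounts(fit)), sum(keep))

  # centroids are definitional means of member feature rows
  feats <- featureValues(pairwiseZDifferences(concatSessions(sim$sessions)))
  for (p in seq_len(fit@k)) {
    expect_equal(unname(centroids(fit)[p, ]),
                 unname(colMeans(feats[labels == p, , drop = FALSE])),
                 tolerance = 1e-9)
  }

  # output files: one clustered file per session, P rows in the summary
  expect_identical(length(list.files(out, pattern = "^Clustered")), 2L)
  ms <- readMeanDistances(file.path(md, "Mouse156DistMean.csv"))
  expect_identical(nrow(centroids(ms)), fit@k)
})

test_that("posture extraction is deterministic under a fixed seed", {
  sim <- simulateSubject(defaultArchetypes(),
                         simulationConfig(sessionsPerSubject = 1,
                                          framesPerSession = 400, seed = 2),
                         "m1", seed = 2)
  f <- pairwiseZDifferences(concatSessions(sim$sessions))
  a <- elbowKmeans(f, clusteringConfig(seed = 17))
  b <- elbowKmeans(f, clusteringConfig(seed = 17))
  expect_identical(a$labels, b$labels)
  expect_identical(a$wcss, b$wcss)
})
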