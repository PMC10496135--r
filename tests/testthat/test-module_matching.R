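test_that("k recommendation follows the MIN(poses) + 1 rule", {
  expect_identical(recommendK(c(9, 8, 11, 10)), 9L)
  expect_identical(recommendK(c(1, 1, 1)), 2L)
  expect_identical(recommendK(c(5, 7, 12)), 6L)
  expect_error(recommendK(integer(0)), "empty")
  expect_error(recommendK(c(3, 0)), "positive")
})

makeSummary <- function(id, centroids, counts = NULL) {
  if (is.null(counts)) counts <- rep(10L, nrow(centroids))
  new("PostureSummary", subjectId = id,
      centroids = matrix(centroids, ncol = 15,
                         dimnames = list(NULL, hotspotPairs())),
      counts = as.integer(counts))
}

test_that("well-separated single-subject matching is a bijection", {
  set.seed(3)
  cen <- matrix(rnorm(4 * 15, sd = 30), ncol = 15)
  map <- matchPostures(list(makeSummary("a", cen)), k = 4,
                       clusteringConfig(seed = 2))
  ent <- moduleEntries(map)
  expect_identical(nrow(ent), 4L)
  expect_identical(sort(unique(ent$bm_id)), 1:4)
})

test_that("identical centroid tables land in the same module (nearest-centroid oracle)", {
  set.seed(9)
  cen <- matrix(rnorm(5 * 15, sd = 25), ncol = 15)
  map <- suppressMessages(
    matchPostures(list(makeSummary("a", cen), makeSummary("b", cen)),
                  k = 5, clusteringConfig(seed = 4)))
  ent <- moduleEntries(map)
  a <- ent[ent$subject_id == "a", ]
  b <- ent[ent$subject_id == "b", ]
  expect_identical(a$bm_id[order(a$posture_id)],
                   b$bm_id[order(b$posture_id)])
  # totality: every (subject, posture) pair appears exactly once
  expect_identical(nrow(ent), 10L)
  expect_identical(anyDuplicated(paste(ent$subject_id, ent$posture_id)), 0L)
})

test_that("matching is invariant to subject input order up to relabeling", {
  set.seed(41)
  sums <- lapply(1:4, function(i)
    makeSummary(paste0("s", i),
                matrix(rnorm(3 * 15, sd = 20), ncol = 15),
                counts = sample(20:60, 3)))
  m1 <- suppressMessages(matchPostures(sums, k = 3,
                                       clusteringConfig(seed = 6)))
  m2 <- suppressMessages(matchPostures(rev(sums), k = 3,
                                       clusteringConfig(seed = 6)))
  e1 <- moduleEntries(m1)
  e2 <- moduleEntries(m2)
  key <- function(e) paste(e$subject_id, e$posture_id)
  e2 <- e2[match(key(e1), key(e2)), ]
  expect_equal(ari(e1$bm_id, e2$bm_id), 1)
})

test_that("invalid matching inputs error", {
  cen <- matrix(rnorm(2 * 15), ncol = 15)
  expect_error(matchPostures(list(makeSummary("a", cen)), k = 5,
                             clusteringConfig(seed = 1)),
               "exceeds")
  expect_error(matchPostures(list(makeSummary("a", cen),
                                  makeSummary("a", cen)), k = 2,
                             clusteringConfig(seed = 1)),
               "duplicate")
})

test_that("cohort matching recovers planted archetype identity", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(nSubjects = 4, sessionsPerSubject = 2,
                          framesPerSession = 600, seed = 13)
  sims <- lapply(1:4, function(i)
    simulateSubject(arch, cfg, sprintf("M%02d", i), seed = 13 + i))
  fits <- lapply(seq_along(sims), function(i)
    extractPostures(sims[[i]]$sessions,
                    clusteringConfig(seed = 100 + i)))

  k <- recommendK(vapply(fits, function(f) f@k, integer(1)))
  map <- suppressMessages(
    matchPostures(lapply(fits, postureSummary), k,
                  clusteringConfig(seed = 77)))

  # each posture's planted archetype: majority vote of member frames
  bmOfFrame <- integer(0)
  archOfFrame <- integer(0)
  for (i in seq_along(sims)) {
    lab <- unlist(postureLabels(fits[[i]]), use.names = FALSE)
    truth <- unlist(sims[[i]]$truth)
    ent <- moduleEntries(map)
    ent <- ent[ent$subject_id == sprintf("M%02d", i), ]
    lut <- ent$bm_id[order(ent$posture_id)]
    keep <- lab > 0
    bmOfFrame <- c(bmOfFrame, lut[lab[keep]])
    archOfFrame <- c(archOfFrame, truth[keep])
  }
  expect_gte(ari(bmOfFrame, archOfFrame), 0.9)
})
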