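test_that("simulation is bit-identical under a fixed seed", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(sessionsPerSubject = 2, framesPerSession = 200,
                          seed = 33)
  a <- simulateSubject(arch, cfg, "m1", seed = 33)
  b <- simulateSubject(arch, cfg, "m1", seed = 33)
  expect_identical(lapply(a$sessions, zMatrix), lapply(b$sessions, zMatrix))
  expect_identical(a$truth, b$truth)

  # and the on-disk cohort as well
  cfg2 <- simulationConfig(nSubjects = 2, sessionsPerSubject = 1,
                           framesPerSession = 100, seed = 9)
  t1 <- tempfile(); t2 <- tempfile()
  simulateCohort(arch, cfg2, t1)
  simulateCohort(arch, cfg2, t2)
  f1 <- list.files(t1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(t2, recursive = TRUE, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("the noiseless limit reproduces archetype profiles exactly", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(sessionsPerSubject = 1, framesPerSession = 150,
                          noiseSd = 0, offsetSd = 0, missingProb = 0,
                          seed = 2)
  sim <- simulateSubject(arch, cfg, "m1", seed = 2)
  z <- zMatrix(sim$sessions[[1]])
  truth <- sim$truth[[1]]
  expect_equal(unname(z),
               unname(archetypeProfiles(arch)[truth, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("empirical dwell times match the configured geometric mean", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(sessionsPerSubject = 1,
                          framesPerSession = 150000, dwellMean = 10,
                          noiseSd = 0, offsetSd = 0, missingProb = 0,
                          minExpressed = 9, seed = 4)
  sim <- simulateSubject(arch, cfg, "m1", seed = 4)
  runs <- rle(sim$truth[[1]])
  lens <- head(runs$lengths, -1)          # last run is truncated
  expect_gt(length(lens), 1e4)
  expect_lt(abs(mean(lens) - cfg@dwellMean) / cfg@dwellMean, 0.05)
})

test_that("missing frames appear at the configured rate", {
  arch <- defaultArchetypes()
  p <- 0.01
  n <- 40000
  cfg <- simulationConfig(sessionsPerSubject = 1, framesPerSession = n,
                          missingProb = p, seed = 11)
  sim <- simulateSubject(arch, cfg, "m1", seed = 11)
  frac <- mean(missingFrames(sim$sessions[[1]]))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("subject body offsets cancel in the feature matrix", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(sessionsPerSubject = 1, framesPerSession = 200,
                          offsetSd = 0, missingProb = 0, seed = 7)
  sim <- simulateSubject(arch, cfg, "m1", seed = 7)
  z <- zMatrix(sim$sessions[[1]])
  fa <- featureValues(pairwiseZDifferences(z))
  fb <- featureValues(pairwiseZDifferences(z + 4.2))  # bigger animal
  expect_equal(fa, fb, tolerance = 1e-12)
})

test_that("cohorts on disk round-trip through layout discovery", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(nSubjects = 3, sessionsPerSubject = 2,
                          framesPerSession = 80, seed = 5)
  td <- tempfile()
  sim <- simulateCohort(arch, cfg, td)
  layout <- discoverLayout(sim$mother)
  expect_identical(length(layout@subjects), 3L)
  expect_true(all(vapply(layout@subjects, length, integer(1)) == 2L))
  # ground truth lives beside, not inside, the mother folder
  expect_false(any(grepl("truth", list.files(sim$mother,
                                             recursive = TRUE))))
  expect_identical(length(list.files(sim$truthDir)), 6L)

  # refusing to clobber an existing non-empty target
  expect_error(simulateCohort(arch, cfg, td), "not empty")
  expect_silent(simulateCohort(arch, cfg, td, force = TRUE))
})

test_that("a subject cannot be asked for more archetypes than exist", {
  arch <- defaultArchetypes()
  cfg <- simulationConfig(minExpressed = 10)
  expect_error(simulateSubject(arch, cfg, "m1"), "exceeds")
})
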