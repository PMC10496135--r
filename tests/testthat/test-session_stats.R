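freqOf <- function(counts, sessions, id = "m1") {
  new("FrequencyTable", subjectId = id,
      counts = matrix(as.integer(counts), ncol = length(sessions),
                      dimnames = list(as.character(seq_len(
                        length(counts) / length(sessions))), sessions)))
}

test_that("session normalization follows (a - b)/(a + b)", {
  # columns: hab = (100, 50), t1 = (100, 100), t2 = (300, 20)
  ft <- freqOf(c(100, 50, 100, 100, 300, 20), c("hab", "t1", "t2"))
  sc <- normalizeSessions(ft, "hab")
  val <- function(bm, s) sc$value[sc$bm_id == bm & sc$session_label == s]
  expect_equal(val(1, "t1"), 0)                       # a = b
  expect_equal(val(1, "t2"), (300 - 100) / 400)       # 0.5
  expect_equal(val(2, "t1"), (100 - 50) / 150)
  expect_equal(val(2, "t2"), (20 - 50) / 70)
  # boundary: module disappears entirely
  ft2 <- freqOf(c(40, 0), c("hab", "t1"))
  expect_equal(normalizeSessions(ft2, "hab")$value, -1)
  # both zero stays defined
  ft3 <- freqOf(c(0, 0), c("hab", "t1"))
  expect_equal(normalizeSessions(ft3, "hab")$value, 0)
  expect_error(normalizeSessions(ft, "sham"), "not present")
})

test_that("normalization is antisymmetric and scale-invariant", {
  set.seed(61)
  for (r in 1:10) {
    a <- sample(0:500, 6)
    b <- sample(0:500, 6)
    fwd <- normalizeSessions(freqOf(c(b, a), c("ref", "test")), "ref")
    bwd <- normalizeSessions(freqOf(c(a, b), c("ref", "test")), "ref")
    expect_equal(fwd$value, -bwd$value, tolerance = 1e-12)
    expect_true(all(abs(fwd$value) <= 1))
    scaled <- normalizeSessions(freqOf(c(3 * b, 3 * a), c("ref", "test")),
                                "ref")
    expect_equal(scaled$value, fwd$value, tolerance = 1e-12)
  }
})

test_that("the unassigned row never enters normalization", {
  counts <- matrix(c(10L, 5L, 2L, 20L, 5L, 1L), ncol = 2,
                   dimnames = list(c("1", "2", "unassigned"),
                                   c("ref", "t1")))
  ft <- new("FrequencyTable", subjectId = "m", counts = counts)
  sc <- normalizeSessions(ft, "ref")
  expect_identical(sort(unique(sc$bm_id)), c(1L, 2L))
})

ethoOf <- function(ids, cat, times) data.frame(subject_id = rep(ids,
                                                                length(cat)),
  category = rep(cat, each = length(ids)),
  time = as.numeric(times))

test_that("module-ethogram correlation matches hand-checkable cases", {
  ids <- paste0("m", 1:4)
  freqs <- lapply(seq_along(ids), function(i)
    freqOf(c(i, 2 * i, 10 - 2 * i), "s01", id = ids[i]))
  # category equal to module-1 time -> r = 1; its negation -> r = -1
  etho <- ethoOf(ids, c("up", "down"), c(2 * (1:4), 20 - 2 * (1:4)))
  res <- correlateBmEthogram(freqs, etho)
  expect_equal(res$r["1", "up"], 1, tolerance = 1e-12)
  expect_equal(res$r["1", "down"], -1, tolerance = 1e-12)
  expect_equal(res$r["2", "up"], 1, tolerance = 1e-12)   # (1..4) vs (2,4,6,8)
  expect_identical(res$n, 4L)
  expect_true(all(res$p[c("1", "2"), ] < 0.05))
})

test_that("correlations agree with a two-pass textbook Pearson", {
  set.seed(29)
  ids <- paste0("m", 1:8)
  freqs <- lapply(ids, function(id)
    freqOf(sample(10:500, 4), "s01", id = id))
  etho <- ethoOf(ids, c("c1", "c2"), runif(16, 0, 300))
  res <- correlateBmEthogram(freqs, etho)
  mat <- vapply(freqs, function(f) frequencyCounts(f)[, 1], numeric(4))
  ethoWide <- matrix(etho$time, ncol = 2)
  for (b in 1:4) for (cc in 1:2) {
    expect_equal(res$r[b, cc], pearsonTwoPass(mat[b, ], ethoWide[, cc]),
                 tolerance = 1e-12)
    ref <- cor.test(mat[b, ], ethoWide[, cc])
    expect_equal(res$p[b, cc], ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are flagged or rejected", {
  ids <- paste0("m", 1:4)
  freqs <- lapply(ids, function(id) freqOf(c(5, 7), "s01", id = id))
  # module 1 time constant across subjects -> flagged NA, not silent zero
  etho <- ethoOf(ids, "cat", 1:4)
  res <- correlateBmEthogram(freqs, etho)
  expect_true(res$constant["1", "cat"])
  expect_true(is.na(res$r["1", "cat"]))

  expect_error(correlateBmEthogram(freqs[1:2], ethoOf(paste0("m", 1:2),
                                                      "cat", 1:2)),
               "at least 3")
  expect_error(correlateBmEthogram(freqs, ethoOf(paste0("x", 1:4),
                                                 "cat", 1:4)),
               "x1")
})
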