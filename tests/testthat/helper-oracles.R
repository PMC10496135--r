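# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# brute-force signed pairwise differences: loop over all i < j pairs
bruteForcePairDiffs <- function(zrow) {
  out <- numeric(0)
  for (i in 1:5) for (j in (i + 1):6) out <- c(out, zrow[i] - zrow[j])
  out
}

# exact minimum-WCSS partition by exhaustive enumeration of all k^n
# assignments (only sensible for tiny n)
enumerateMinWCSS <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 1e6)
  best <- list(wcss = Inf, labels = NULL)
  lab <- rep(1L, n)
  for (code in 0:(k^n - 1)) {
    c0 <- code
    for (i in 1:n) {
      lab[i] <- (c0 %% k) + 1L
      c0 <- c0 %/% k
    }
    if (length(unique(lab)) < k) next
    w <- 0
    for (g in 1:k) {
      rows <- x[lab == g, , drop = FALSE]
      ctr <- colMeans(rows)
      w <- w + sum(sweep(rows, 2, ctr)^2)
    }
    if (w < best$wcss) best <- list(wcss = w, labels = lab)
  }
  best
}

# textbook two-pass Pearson correlation
pearsonTwoPass <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# adjusted Rand index between two labelings (chance-corrected agreement)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted-cluster feature matrix: nPer points around each of k centers
plantedClusters <- function(centers, nPer, sd, seed) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
    matrix(rnorm(nPer * ncol(centers), 0, sd), ncol = ncol(centers)) +
      matrix(centers[g, ], nPer, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = nPer))
}

# a quick valid TrackingSession from a z matrix
makeSession <- function(z, id = "m1", label = "s01", fps = 25) {
  TrackingSession(id, z, sessionLabel = label, fps = fps)
}
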