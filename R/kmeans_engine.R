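## Seeded k-means engine shared by posture extraction (step 1, elbow over k)
## and posture matching (step 2, fixed k). Initialization is k-means++ drawn
## from R's RNG; the Lloyd iteration lives in C++ (lloyd_cpp) with a
## lowest-index tie-break so the whole fit is a pure function of (data,
## config, RNG state).

## k-means++ seeding: first center uniform, later centers with probability
## proportional to the squared distance to the nearest chosen center.
kmeansppInit <- function(x, k) {
  n <- nrow(x)
  rx2 <- rowSums(x * x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- pmax(rx2 - 2 * drop(x %*% x[idx[1L], ]) + sum(x[idx[1L], ]^2), 0)
    for (j in 2L:k) {
      tot <- sum(d2)
      if (!is.finite(tot) || tot <= 0) {
        ## all mass on already-chosen points (duplicates): take the first
        ## index not yet used, deterministically
        idx[j] <- setdiff(seq_len(n), idx[seq_len(j - 1L)])[1L]
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      nd <- pmax(rx2 - 2 * drop(x %*% x[idx[j], ]) + sum(x[idx[j], ]^2), 0)
      d2 <- pmin(d2, nd)
    }
  }
  x[idx, , drop = FALSE]
}

## Best-of-replicates k-means at fixed k. Consumes RNG; callers wrap in
## withSeed().
kmeansFit <- function(x, k, replicates = 10L, maxIter = 300L) {
  stopifnot(k >= 1L, nrow(x) >= 1L)
  if (k == 1L) {
    center <- matrix(colMeans(x), nrow = 1L)
    wcss <- sum(sweep(x, 2L, center[1L, ])^2)
    return(list(labels = rep.int(1L, nrow(x)), centers = center,
                wcss = wcss, iterations = 0L))
  }
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- lloyd_cpp(x, kmeansppInit(x, k), as.integer(maxIter))
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' Elbow-criterion k-means over a posture feature matrix
#'
#' Scans k = 1..kMax, keeping for each k the best of \code{replicates}
#' seeded k-means++ runs, and picks the smallest k whose explained-variance
#' fraction V(k) = 1 - WCSS(k)/WCSS(1) reaches \code{varianceCutoff}. Frames
#' flagged missing receive label 0 and are excluded from the fit. When all
#' frames are identical (WCSS(1) = 0) the elbow degenerates to k = 1.
#'
#' @param features a [DistanceFeatureMatrix-class] (or plain numeric matrix).
#' @param config a [ClusteringConfig-class]; \code{config@seed} makes the
#'   result reproducible.
#' @return A list with elements \code{labels} (per-frame posture labels, 0
#'   for missing frames), \code{k} (chosen cluster number), \code{wcss}
#'   (best within-cluster sum of squares per candidate k), and
#'   \code{explained} (V(k) per candidate k).
#' @export
#' @examples
#' z <- matrix(rep(c(0, 5, 9), each = 30) + rnorm(90, sd = 0.1), ncol = 1)
#' x <- cbind(z, z, z, z, z, z)[, 1:6] * (1:6 / 3)
#' f <- pairwiseZDifferences(x)
#' fit <- elbowKmeans(f, clusteringConfig(kMax = 6, seed = 1))
#' fit$k
elbowKmeans <- function(features, config = clusteringConfig()) {
  vals <- if (is(features, "DistanceFeatureMatrix")) features@values
          else as.matrix(features)
  ok <- complete.cases(vals) & rowSums(!is.finite(vals)) == 0L
  if (!any(ok)) stop("no non-missing frames available for clustering")
  x <- vals[ok, , drop = FALSE]

  nDistinct <- nrow(unique(x))
  kMax <- config@kMax
  if (kMax > nDistinct) {
    message("kMax clamped from ", kMax, " to ", nDistinct,
            " distinct feature rows")
    kMax <- nDistinct
  }

  fits <- withSeed(config@seed, {
    lapply(seq_len(kMax), function(k)
      kmeansFit(x, k, replicates = config@replicates,
                maxIter = config@maxIter))
  })
  wcss <- vapply(fits, `[[`, numeric(1), "wcss")

  if (wcss[1L] <= 0) {
    chosen <- 1L
    explained <- c(0, rep(NA_real_, kMax - 1L))
  } else {
    explained <- 1 - wcss / wcss[1L]
    explained[1L] <- 0
    hit <- which(explained >= config@varianceCutoff)
    chosen <- if (length(hit)) hit[1L] else kMax
  }

  labels <- integer(nrow(vals))
  labels[ok] <- fits[[chosen]]$labels
  list(labels = labels, k = chosen, wcss = wcss, explained = explained)
}
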