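## Step 2: pool every subject's posture centroids and k-means them into
## cohort-level behavioral modules (BMs), automatically matching postures
## across animals.

#' Recommended module count for cross-subject matching
#'
#' The rule of thumb for the second clustering: k = MIN(poses) + 1, where
#' MIN(poses) is the smallest number of postures discovered in any single
#' subject. With a cohort minimum of 8 postures this recommends 9 modules.
#'
#' @param postureCounts vector of per-subject posture counts.
#' @return Integer, the recommended k.
#' @export
#' @examples
#' recommendK(c(9, 8, 11, 10))  # 9
recommendK <- function(postureCounts) {
  if (length(postureCounts) == 0)
    stop("posture count vector is empty")
  postureCounts <- as.integer(postureCounts)
  if (anyNA(postureCounts) || any(postureCounts < 1L))
    stop("posture counts must be positive integers")
  min(postureCounts) + 1L
}

#' Match postures across subjects into behavioral modules
#'
#' Pools the posture centroid rows of all subjects and clusters them with
#' the same seeded k-means engine used in step 1, at fixed k (no elbow).
#' Each posture's behavioral module is its centroid's cluster. Centroid rows
#' enter unweighted by default; \code{weighted} replicates each row's
#' contribution by its frame count when counts are available. Two postures
#' of the same subject may legitimately land in the same module (logged via
#' message); modules are renumbered by descending total frame count across
#' the cohort.
#'
#' @param summaries list of [PostureSummary-class], one per subject.
#' @param k number of behavioral modules (see [recommendK()]).
#' @param config a [ClusteringConfig-class]; only \code{replicates},
#'   \code{seed} and \code{maxIter} are used.
#' @param weighted weight centroid rows by posture frame counts.
#' @return A [ModuleMap-class].
#' @export
matchPostures <- function(summaries, k, config = clusteringConfig(),
                          weighted = FALSE) {
  stopifnot(length(summaries) >= 1L)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")

  pooled <- do.call(rbind, lapply(summaries, function(s) s@centroids))
  keys <- do.call(rbind, lapply(summaries, function(s)
    data.frame(subject_id = s@subjectId,
               posture_id = seq_len(nrow(s@centroids)),
               count = s@counts, stringsAsFactors = FALSE)))
  if (anyDuplicated(paste(keys$subject_id, keys$posture_id)))
    stop("duplicate (subject, posture) keys in pooled summaries")
  if (k > nrow(pooled))
    stop("k = ", k, " exceeds the ", nrow(pooled),
         " pooled posture centroids")

  x <- pooled
  rowOf <- seq_len(nrow(pooled))
  if (weighted) {
    if (anyNA(keys$count))
      stop("weighted matching requires posture frame counts")
    rowOf <- rep(seq_len(nrow(pooled)), keys$count)
    x <- pooled[rowOf, , drop = FALSE]
  }

  fit <- withSeed(config@seed,
                  kmeansFit(x, k, replicates = config@replicates,
                            maxIter = config@maxIter))
  bm <- integer(nrow(pooled))
  bm[rowOf] <- fit$labels   # for weighted fits the last copy wins; copies agree

  ## renumber modules by descending total frames (fall back to posture
  ## multiplicity when counts were not stored)
  w <- if (anyNA(keys$count)) rep(1L, nrow(keys)) else keys$count
  tot <- vapply(seq_len(k), function(j) sum(w[bm == j]), numeric(1))
  relabel <- integer(k)
  relabel[order(tot, decreasing = TRUE)] <- seq_len(k)
  bm <- relabel[bm]

  entries <- data.frame(subject_id = keys$subject_id,
                        posture_id = keys$posture_id,
                        bm_id = as.integer(bm), stringsAsFactors = FALSE)
  merges <- tapply(entries$bm_id, entries$subject_id,
                   function(b) sum(duplicated(b)))
  if (any(merges > 0))
    message("merged postures within subject(s): ",
            paste(names(merges)[merges > 0], collapse = ", "))
  new("ModuleMap", entries = entries, k = k)
}
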