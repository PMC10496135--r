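## Step 1: per subject, concatenate z across sessions, derive the 15 signed
## pairwise height differences per frame, and discover postures with
## elbow-criterion k-means.

#' Concatenate a subject's sessions into one z timeline
#'
#' Stacks the z matrices of all sessions of one subject in session order,
#' recording each row's (session, frame) origin so downstream outputs can be
#' split back per session.
#'
#' @param sessions list of [TrackingSession-class] for a single subject.
#' @return An internal timeline object carrying the stacked z matrix, the
#'   per-frame missingness flag, and the frame origin table.
#' @export
concatSessions <- function(sessions) {
  stopifnot(length(sessions) >= 1L)
  ids <- unname(vapply(sessions, function(s) s@subjectId, character(1)))
  if (length(unique(ids)) != 1L)
    stop("sessions belong to different subjects: ",
         paste(unique(ids), collapse = ", "))
  fpsAll <- vapply(sessions, function(s) s@fps, numeric(1))
  z <- do.call(rbind, lapply(sessions, function(s) s@z))
  missing <- unlist(lapply(sessions, function(s) s@missing),
                    use.names = FALSE)
  origin <- do.call(rbind, lapply(sessions, function(s)
    data.frame(session_label = s@sessionLabel, frame = seq_len(nrow(s@z)),
               stringsAsFactors = FALSE)))
  new("ZTimeline", subjectId = ids[1L], z = z, missing = missing,
      origin = origin, fps = fpsAll[1L])
}

#' Signed pairwise height differences
#'
#' Converts an N x 6 z-coordinate timeline into the N x 15 feature matrix of
#' signed differences z_i - z_j over all hotspot pairs i < j in canonical
#' order. The sign is kept deliberately: whether the nose sits above or
#' below the tail is the behavioral signal. Because any constant added to
#' all six hotspots cancels in every difference, per-subject body-size
#' offsets drop out of the features. Frames flagged missing yield
#' non-finite rows that stay flagged.
#'
#' @param x an N x 6 numeric matrix or the timeline from
#'   [concatSessions()].
#' @param absolute use |z_i - z_j| instead of the signed difference.
#' @return A [DistanceFeatureMatrix-class].
#' @export
#' @examples
#' featureValues(pairwiseZDifferences(matrix(c(5, 4, 3, 2, 1, 0), nrow = 1)))
pairwiseZDifferences <- function(x, absolute = FALSE) {
  if (is(x, "ZTimeline")) {
    z <- x@z; missing <- x@missing; origin <- x@origin
  } else {
    z <- as.matrix(x)
    missing <- rowSums(!is.finite(z)) > 0L
    origin <- data.frame(session_label = "session", frame = seq_len(nrow(z)),
                         stringsAsFactors = FALSE)
  }
  if (ncol(z) != 6L)
    stop("z timeline must have exactly 6 hotspot columns, found ", ncol(z))
  if (nrow(z) < 1L) stop("z timeline must contain at least one frame")
  P <- matrix(0, nrow = 6L, ncol = 15L)
  for (p in seq_len(15L)) {
    P[.PAIRS[p, 1L], p] <- 1
    P[.PAIRS[p, 2L], p] <- -1
  }
  vals <- z %*% P
  if (absolute) vals <- abs(vals)
  colnames(vals) <- hotspotPairs()
  new("DistanceFeatureMatrix", values = vals, origin = origin,
      missing = missing)
}

#' Extract postures for one subject
#'
#' Orchestrates step 1: concatenates the subject's sessions, computes the
#' pairwise height-difference features, clusters them with
#' [elbowKmeans()], and renumbers the resulting postures by descending frame
#' count (posture 1 is the most frequent). Centroids are recomputed as the
#' plain mean of each posture's member feature rows. When \code{outDir} is
#' given, the per-session clustered-frame files and the subject's
#' mean-distance file are written there; \code{meanDistDir} additionally
#' receives a copy of the mean-distance file (the conventional
#' "Mean Distances" folder of the mother folder).
#'
#' @param sessions list of [TrackingSession-class] for one subject.
#' @param config a [ClusteringConfig-class].
#' @param absolute cluster absolute rather than signed differences.
#' @param outDir optional output directory (normally the subject's folder).
#' @param meanDistDir optional directory for the mean-distance copy.
#' @return A [PostureFit-class].
#' @export
extractPostures <- function(sessions, config = clusteringConfig(),
                            absolute = FALSE, outDir = NULL,
                            meanDistDir = NULL) {
  timeline <- concatSessions(sessions)
  feats <- pairwiseZDifferences(timeline, absolute = absolute)
  fit <- elbowKmeans(feats, config)

  k <- fit$k
  counts <- tabulate(fit$labels[fit$labels > 0L], nbins = k)
  ord <- order(counts, decreasing = TRUE)     # stable: ties keep low index
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- integer(length(fit$labels))
  pos <- fit$labels > 0L
  labels[pos] <- relabel[fit$labels[pos]]

  cen <- matrix(NA_real_, nrow = k, ncol = 15L,
                dimnames = list(NULL, hotspotPairs()))
  for (p in seq_len(k)) {
    rows <- which(labels == p)
    cen[p, ] <- colMeans(feats@values[rows, , drop = FALSE])
  }
  summary <- new("PostureSummary", subjectId = timeline@subjectId,
                 centroids = cen, counts = as.integer(sort(counts,
                                                           decreasing = TRUE)))

  perSession <- split(labels, factor(feats@origin$session_label,
                                     levels = unique(feats@origin$session_label)))
  perSession <- lapply(perSession, as.integer)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      writeClustered(s, perSession[[s@sessionLabel]],
                     file.path(outDir, paste0("Clustered", s@subjectId, "_",
                                              s@sessionLabel, ".csv")))
    }
    mdPath <- file.path(outDir, paste0("Mouse", timeline@subjectId,
                                       "DistMean.csv"))
    writeMeanDistances(summary, mdPath)
    if (!is.null(meanDistDir)) {
      dir.create(meanDistDir, recursive = TRUE, showWarnings = FALSE)
      file.copy(mdPath, file.path(meanDistDir, basename(mdPath)),
                overwrite = TRUE)
    }
  }

  new("PostureFit", summary = summary, labels = perSession,
      wcss = fit$wcss, explained = fit$explained, k = as.integer(k))
}
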