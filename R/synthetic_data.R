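## Synthetic cohort generator: plants known posture archetypes in
## DLC-3D-style tracking files so every pipeline stage can be validated
## against ground truth without any recordings.

#' Default posture archetypes
#'
#' Nine stylized hotspot-height profiles used as planted ground truth.
#' Each profile carries a coarse postural motif (a nose-high rearing-like
#' pose, a mid-back-apex hunch-like pose, a tail-high stretched pose, and so
#' on), but the set is deliberately *not* biomechanical: the nine shapes are
#' spread to be near-equidistant in the 15-dimensional difference-feature
#' space (pairwise feature distances between 18 and 30 camera units, i.e.
#' more than ten times the default tracking-noise s.d. of
#' [simulationConfig()]), because realistic postures cluster along a few
#' shape directions that no variance-based cluster number criterion could
#' tell apart. A fixture must make ground truth recoverable; these profiles
#' trade anatomy for that.
#'
#' @return An [ArchetypeSet-class] with 9 profiles.
#' @export
#' @examples
#' defaultArchetypes()
#' archetypeSeparation(defaultArchetypes())
defaultArchetypes <- function() {
  p <- rbind(
    nose_high    = c(12.9,  6.0,  8.9,  6.2,  5.9,  8.1),
    front_high   = c(11.0,  9.5,  7.2,  8.3,  8.8,  3.2),
    mid_apex     = c( 7.9,  4.2,  8.7, 12.5,  7.8,  6.9),
    alternating  = c( 7.6, 10.4,  4.8, 10.7,  4.9,  9.7),
    tail_high    = c( 7.5,  5.8,  4.9,  7.4, 10.8, 11.6),
    caudal_peak  = c( 4.2,  9.1,  7.9,  9.8, 11.4,  5.6),
    neck_peak    = c( 4.5,  6.1, 11.3,  6.7,  8.9, 10.6),
    eyes_peak    = c( 9.2, 11.6,  7.0,  3.5,  7.9,  8.7),
    back_ridge   = c( 6.9, 10.0, 12.2,  8.0,  4.9,  6.1))
  colnames(p) <- hotspotNames()
  ArchetypeSet(p)
}

#' Construct an ArchetypeSet
#'
#' @param profiles numeric matrix A x 6 of hotspot heights, one archetype
#'   per row (rownames optional).
#' @return An [ArchetypeSet-class].
#' @export
ArchetypeSet <- function(profiles) {
  profiles <- as.matrix(profiles)
  colnames(profiles) <- hotspotNames()
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("archetype", seq_len(nrow(profiles)))
  new("ArchetypeSet", profiles = profiles)
}

#' Minimum archetype separation in feature space
#'
#' Smallest pairwise Euclidean distance between archetypes after the
#' height profiles are mapped to the 15 signed pairwise differences —
#' the separation that matters for posture clustering.
#'
#' @param archetypes an [ArchetypeSet-class].
#' @return Numeric scalar.
#' @export
archetypeSeparation <- function(archetypes) {
  stopifnot(is(archetypes, "ArchetypeSet"))
  f <- featureValues(pairwiseZDifferences(archetypes@profiles))
  min(dist(f))
}

#' Simulate one subject's tracking sessions
#'
#' Draws a subject-specific archetype subset (size uniform between
#' \code{minExpressed} and the number of archetypes), then switches between
#' archetypes with a semi-Markov process: dwell times are geometric with the
#' configured mean, and the next archetype is drawn uniformly among the
#' others of the subset. The z coordinate of each frame is archetype profile
#' + a per-subject body-size offset (constant across hotspots) + i.i.d.
#' Gaussian noise; whole frames go missing independently with the configured
#' probability. Bit-identical output under a fixed seed.
#'
#' @param archetypes an [ArchetypeSet-class].
#' @param config a [SimulationConfig-class].
#' @param subjectId animal ID for the generated sessions.
#' @param seed RNG seed for this subject (defaults to \code{config@seed}).
#' @return A list with \code{sessions} (list of [TrackingSession-class])
#'   and \code{truth} (list of integer vectors: the planted archetype of
#'   every frame, including frames later lost to missing tracking).
#' @export
simulateSubject <- function(archetypes, config = simulationConfig(),
                            subjectId = "M01", seed = config@seed) {
  stopifnot(is(archetypes, "ArchetypeSet"), is(config, "SimulationConfig"))
  A <- nrow(archetypes@profiles)
  if (config@minExpressed > A)
    stop("minExpressed (", config@minExpressed, ") exceeds the ", A,
         " available archetypes")
  withSeed(seed, {
    size <- if (config@minExpressed == A) A
            else sample(config@minExpressed:A, 1L)
    subset <- sort(sample.int(A, size))
    offset <- rnorm(1L, 0, config@offsetSd)
    sessions <- vector("list", config@sessionsPerSubject)
    truth <- vector("list", config@sessionsPerSubject)
    for (j in seq_len(config@sessionsPerSubject)) {
      lab <- .semiMarkovLabels(subset, config@framesPerSession,
                               config@dwellMean)
      z <- archetypes@profiles[lab, , drop = FALSE] + offset +
        matrix(rnorm(length(lab) * 6L, 0, config@noiseSd), ncol = 6L)
      lost <- runif(length(lab)) < config@missingProb
      z[lost, ] <- NA_real_
      sessions[[j]] <- TrackingSession(subjectId, z,
                                       sessionLabel = sprintf("s%02d", j),
                                       fps = config@fps)
      truth[[j]] <- lab
    }
    names(sessions) <- names(truth) <- sprintf("s%02d",
                                               seq_len(config@sessionsPerSubject))
    list(sessions = sessions, truth = truth)
  })
}

## semi-Markov switching: geometric dwell (mean dwellMean, support >= 1),
## next state uniform among the other members of the subset.
.semiMarkovLabels <- function(subset, nFrames, dwellMean) {
  lab <- integer(nFrames)
  pos <- 1L
  cur <- subset[sample.int(length(subset), 1L)]
  while (pos <= nFrames) {
    dwell <- 1L + rgeom(1L, 1 / dwellMean)
    end <- min(pos + dwell - 1L, nFrames)
    lab[pos:end] <- cur
    pos <- end + 1L
    if (length(subset) > 1L) {
      others <- subset[subset != cur]
      cur <- others[sample.int(length(others), 1L)]
    }
  }
  lab
}

#' Simulate a cohort mother folder on disk
#'
#' Writes a complete mother-folder layout — one subfolder per subject, one
#' DLC-3D-dialect tracking CSV per session, file names carrying the subject
#' ID — plus per-session ground-truth label files in a sibling "truth"
#' directory (never inside the mother folder, which must contain only
#' tracking data).
#'
#' @param archetypes an [ArchetypeSet-class].
#' @param config a [SimulationConfig-class]; subject i is generated with
#'   seed \code{config@seed + i}.
#' @param path output directory; the mother folder is created at
#'   \code{<path>/cohort} and ground truth at \code{<path>/truth}.
#' @param force overwrite an existing non-empty output directory.
#' @return A list with \code{mother}, \code{truthDir}, \code{subjects}, and
#'   \code{truth} (nested list of per-frame archetype labels), invisibly.
#' @export
simulateCohort <- function(archetypes, config = simulationConfig(), path,
                           force = FALSE) {
  stopifnot(is(archetypes, "ArchetypeSet"), is(config, "SimulationConfig"))
  if (dir.exists(path) && length(list.files(path)) > 0 && !force)
    stop("output directory exists and is not empty: ", path,
         " (use force = TRUE to overwrite)")
  mother <- file.path(path, "cohort")
  truthDir <- file.path(path, "truth")
  dir.create(mother, recursive = TRUE, showWarnings = FALSE)
  dir.create(truthDir, recursive = TRUE, showWarnings = FALSE)

  ids <- sprintf("M%02d", seq_len(config@nSubjects))
  truthAll <- list()
  for (i in seq_along(ids)) {
    sim <- simulateSubject(archetypes, config, subjectId = ids[i],
                           seed = config@seed + i)
    subjDir <- file.path(mother, ids[i])
    dir.create(subjDir, showWarnings = FALSE)
    for (j in seq_along(sim$sessions)) {
      s <- sim$sessions[[j]]
      writeTrackingCSV(s, file.path(subjDir, paste0(ids[i], "_",
                                                    s@sessionLabel, ".csv")))
      write.table(
        data.frame(frame = seq_along(sim$truth[[j]]),
                   archetype = sim$truth[[j]]),
        file.path(truthDir, paste0(ids[i], "_", s@sessionLabel,
                                   "_truth.csv")),
        sep = ",", row.names = FALSE, quote = FALSE)
    }
    truthAll[[ids[i]]] <- sim$truth
  }
  invisible(list(mother = mother, truthDir = truthDir, subjects = ids,
                 truth = truthAll))
}
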