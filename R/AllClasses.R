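#' TrackingSession: one recording session for one subject
#'
#' Holds the per-frame vertical (z) coordinates of the six canonical bodily
#' hotspots for a single subject and session, together with the acquisition
#' frame rate and a per-frame missingness flag. Frames where any hotspot z is
#' absent or non-numeric are kept in the timeline (so frame indices stay
#' aligned across sessions) but flagged, excluded from clustering, and later
#' labeled with the sentinel 0 ("unassigned").
#'
#' @slot subjectId animal identifier (character scalar).
#' @slot sessionLabel label giving the session's place in the experiment
#'   (e.g. "habituation", "sham", "t1").
#' @slot z numeric matrix, frames x 6, columns in canonical hotspot order
#'   (camera units).
#' @slot fps frames per second (positive scalar; 25 for a typical setup).
#' @slot missing logical vector, one entry per frame; \code{TRUE} when any
#'   hotspot z is non-finite.
#'
#' @seealso [readTrackingCSV()], [concatSessions()]
#' @export
setClass("TrackingSession",
  representation(subjectId = "character", sessionLabel = "character",
                 z = "matrix", fps = "numeric", missing = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
    if (ncol(object@z) != 6L || !identical(colnames(object@z), hotspotNames()))
      msg <- c(msg, "z must have exactly 6 columns named in canonical hotspot order")
    if (nrow(object@z) < 1L) msg <- c(msg, "z must contain at least one frame")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      msg <- c(msg, "fps must be a positive scalar")
    if (length(object@missing) != nrow(object@z))
      msg <- c(msg, "missing flag must have one entry per frame")
    bad <- rowSums(!is.finite(object@z)) > 0L
    if (!identical(unname(bad), unname(object@missing)))
      msg <- c(msg, "missing flag inconsistent with non-finite z entries")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TrackingSession
#'
#' @param subjectId animal identifier.
#' @param z frames x 6 numeric matrix of hotspot z coordinates (canonical
#'   column order; column names are set automatically).
#' @param sessionLabel session label; defaults to "session".
#' @param fps frames per second.
#' @return A [TrackingSession-class] object.
#' @export
#' @examples
#' z <- matrix(rnorm(60), ncol = 6)
#' TrackingSession("156", z, sessionLabel = "of", fps = 25)
TrackingSession <- function(subjectId, z, sessionLabel = "session", fps = 25) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  dimnames(z) <- list(NULL, hotspotNames())
  new("TrackingSession", subjectId = as.character(subjectId),
      sessionLabel = as.character(sessionLabel), z = z, fps = as.numeric(fps),
      missing = rowSums(!is.finite(z)) > 0L)
}

#' CohortLayout: discovered mother-folder structure
#'
#' One entry per subject subfolder of the mother folder, each holding the
#' session tracking files in deterministic (natural-sorted) order.
#'
#' @slot root path of the mother folder.
#' @slot subjects named list; one character vector of session file paths per
#'   subject ID.
#' @seealso [discoverLayout()]
#' @export
setClass("CohortLayout",
  representation(root = "character", subjects = "list"),
  validity = function(object) {
    if (length(object@subjects) < 1L) return("no subjects in layout")
    if (is.null(names(object@subjects))) return("subjects list must be named")
    TRUE
  })

## Internal: a subject's concatenated z timeline with per-frame origin,
## produced by concatSessions().
setClass("ZTimeline",
  representation(subjectId = "character", z = "matrix", missing = "logical",
                 origin = "data.frame", fps = "numeric"))

#' DistanceFeatureMatrix: signed pairwise height differences
#'
#' The 15-column feature matrix of SEB-style posture extraction: for each
#' frame, the signed difference z_i - z_j for every hotspot pair i < j in
#' canonical order. Subject-specific body-size offsets (a constant added to
#' all hotspots) cancel exactly in these differences.
#'
#' @slot values numeric matrix N x 15; columns named by [hotspotPairs()].
#' @slot origin data.frame with one row per frame (columns
#'   \code{session_label}, \code{frame}) recording where each row came from.
#' @slot missing logical, per-row missingness carried from the timeline.
#' @seealso [pairwiseZDifferences()]
#' @export
setClass("DistanceFeatureMatrix",
  representation(values = "matrix", origin = "data.frame",
                 missing = "logical"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@values) != 15L)
      msg <- c(msg, "feature matrix must have exactly 15 columns (C(6,2) pairs)")
    if (nrow(object@values) != nrow(object@origin))
      msg <- c(msg, "origin must have one row per frame")
    if (length(object@missing) != nrow(object@values))
      msg <- c(msg, "missing flag must have one entry per frame")
    if (is.null(msg)) TRUE else msg
  })

#' ClusteringConfig: parameters of the elbow k-means engine
#'
#' @slot kMax largest candidate cluster number scanned by the elbow (default
#'   20).
#' @slot varianceCutoff explained-variance fraction at which the elbow stops
#'   (default 0.95); the chosen k is the smallest k whose explained variance
#'   V(k) = 1 - WCSS(k)/WCSS(1) reaches the cutoff.
#' @slot replicates k-means++ restarts per candidate k; the best (lowest
#'   within-cluster sum of squares) run is kept (default 10).
#' @slot seed integer seed making the whole clustering reproducible.
#' @slot maxIter Lloyd iteration cap per run (default 300).
#' @export
setClass("ClusteringConfig",
  representation(kMax = "integer", varianceCutoff = "numeric",
                 replicates = "integer", seed = "integer",
                 maxIter = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@kMax < 1L) msg <- c(msg, "kMax must be >= 1")
    if (object@varianceCutoff <= 0 || object@varianceCutoff >= 1)
      msg <- c(msg, "varianceCutoff must lie strictly between 0 and 1")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ClusteringConfig
#'
#' @param kMax,varianceCutoff,replicates,seed,maxIter see
#'   [ClusteringConfig-class].
#' @return A ClusteringConfig.
#' @export
#' @examples
#' clusteringConfig(seed = 7)
clusteringConfig <- function(kMax = 20, varianceCutoff = 0.95, replicates = 10,
                             seed = 1, maxIter = 300) {
  new("ClusteringConfig", kMax = as.integer(kMax),
      varianceCutoff = as.numeric(varianceCutoff),
      replicates = as.integer(replicates), seed = as.integer(seed),
      maxIter = as.integer(maxIter))
}

#' PostureSummary: per-subject posture centroids
#'
#' Mean 15-distance vectors of the postures discovered in one subject.
#' Posture IDs are 1..P ordered by descending frame count.
#'
#' @slot subjectId animal identifier.
#' @slot centroids numeric matrix P x 15; row p is the mean feature vector of
#'   all frames labeled with posture p.
#' @slot counts integer vector of frames per posture (NA when reloaded from a
#'   mean-distance file, which does not store counts).
#' @export
setClass("PostureSummary",
  representation(subjectId = "character", centroids = "matrix",
                 counts = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@centroids) < 1L) msg <- c(msg, "at least one posture required")
    if (ncol(object@centroids) != 15L)
      msg <- c(msg, "centroids must have 15 columns")
    if (length(object@counts) != nrow(object@centroids))
      msg <- c(msg, "counts must have one entry per posture")
    if (is.null(msg)) TRUE else msg
  })

## Internal-ish container for the full step-1 result of one subject: summary
## plus the per-session frame labels and the elbow diagnostics.
#' PostureFit: full posture-extraction result for one subject
#'
#' @slot summary the [PostureSummary-class].
#' @slot labels named list of integer vectors (one per session) of per-frame
#'   posture IDs; 0 marks frames with missing tracking.
#' @slot wcss best within-cluster sum of squares for each candidate k.
#' @slot explained explained-variance fraction V(k) for each candidate k.
#' @slot k the elbow-chosen number of postures.
#' @export
setClass("PostureFit",
  representation(summary = "PostureSummary", labels = "list",
                 wcss = "numeric", explained = "numeric", k = "integer"))

#' ModuleMap: posture-to-behavioral-module assignment
#'
#' Output of cross-subject posture matching: every (subject, posture) pair
#' from step 1 mapped to a cohort-level behavioral module (BM) ID. Two
#' postures of the same subject may share a BM (they are merged downstream).
#'
#' @slot entries data.frame with columns \code{subject_id},
#'   \code{posture_id}, \code{bm_id}.
#' @slot k the chosen module count; BM IDs are a subset of 1..k.
#' @export
setClass("ModuleMap",
  representation(entries = "data.frame", k = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("subject_id", "posture_id", "bm_id")
    if (!all(need %in% names(object@entries)))
      msg <- c(msg, "entries must have subject_id, posture_id, bm_id columns")
    else {
      key <- paste(object@entries$subject_id, object@entries$posture_id)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (subject, posture) keys in module map")
      if (any(object@entries$bm_id < 1L | object@entries$bm_id > object@k))
        msg <- c(msg, "bm_id outside 1..k")
    }
    if (is.null(msg)) TRUE else msg
  })

#' LabeledSession: per-frame posture and module labels
#'
#' @slot subjectId,sessionLabel identity of the session.
#' @slot posture integer per-frame posture ID (0 = unassigned).
#' @slot bm integer per-frame behavioral-module ID (0 = unassigned).
#' @slot fps frames per second.
#' @export
setClass("LabeledSession",
  representation(subjectId = "character", sessionLabel = "character",
                 posture = "integer", bm = "integer", fps = "numeric"),
  validity = function(object) {
    if (length(object@posture) != length(object@bm))
      return("posture and bm labels must have equal length")
    TRUE
  })

#' FrequencyTable: frames per behavioral module and session
#'
#' Rows are behavioral modules (plus an "unassigned" row when any frame has
#' missing tracking), columns are sessions in experiment order; cell (b, s)
#' counts the frames of session s assigned to BM b, so each column sums to
#' that session's frame count.
#'
#' @slot subjectId animal identifier.
#' @slot counts integer matrix BM x sessions with dimnames.
#' @export
setClass("FrequencyTable",
  representation(subjectId = "character", counts = "matrix"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' BoutTable: run-length-encoded behavioral-module stream
#'
#' Maximal runs of identical BM labels within one session. Bouts tile the
#' session exactly: lengths sum to the session frame count, and consecutive
#' bouts carry different BM IDs. Bouts never span session boundaries.
#'
#' @slot subjectId,sessionLabel identity of the session.
#' @slot bouts data.frame with columns \code{bm_id}, \code{start}
#'   (1-based frame), \code{length} (frames, >= 1).
#' @slot fps frames per second used for duration conversion.
#' @slot nFrames total frames in the encoded stream.
#' @export
setClass("BoutTable",
  representation(subjectId = "character", sessionLabel = "character",
                 bouts = "data.frame", fps = "numeric", nFrames = "integer"),
  validity = function(object) {
    msg <- NULL
    b <- object@bouts
    if (!all(c("bm_id", "start", "length") %in% names(b)))
      msg <- c(msg, "bouts needs bm_id, start, length columns")
    else {
      if (any(b$length < 1L)) msg <- c(msg, "bout lengths must be >= 1")
      if (sum(b$length) != object@nFrames)
        msg <- c(msg, "bout lengths must tile the session exactly")
      if (nrow(b) > 1L && any(b$bm_id[-1L] == b$bm_id[-nrow(b)]))
        msg <- c(msg, "consecutive bouts must differ in bm_id")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ArchetypeSet: planted posture archetypes for simulation
#'
#' Each row is a hotspot-height profile (arbitrary camera units) for one
#' idealized posture, e.g. a rearing-like profile with nose and eyes high or
#' a hunched profile peaking at the mid back.
#'
#' @slot profiles numeric matrix A x 6 (canonical hotspot columns), rownames
#'   are archetype names.
#' @export
setClass("ArchetypeSet",
  representation(profiles = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@profiles) < 1L) msg <- c(msg, "need at least one archetype")
    if (ncol(object@profiles) != 6L) msg <- c(msg, "profiles must have 6 hotspot columns")
    if (anyDuplicated(object@profiles, MARGIN = 1))
      msg <- c(msg, "archetype rows must be pairwise distinct")
    if (is.null(msg)) TRUE else msg
  })

#' SimulationConfig: synthetic cohort generator settings
#'
#' Defaults emulate a five-session whisker-stimulation-style experiment: 12
#' subjects, 5 sessions of 4500 frames at 25 fps, semi-Markov archetype
#' switching with geometric dwell times, per-subject additive body-size
#' offsets, i.i.d. Gaussian tracking noise, and occasional missing frames.
#'
#' @slot nSubjects number of animals.
#' @slot sessionsPerSubject sessions per animal.
#' @slot framesPerSession frames per session.
#' @slot dwellMean mean bout length in frames of the geometric dwell law.
#' @slot noiseSd tracking noise s.d. per hotspot (camera units).
#' @slot offsetSd s.d. of the per-subject additive z offset (body size).
#' @slot minExpressed each subject expresses at least this many of the A
#'   archetypes (subset size drawn uniformly from minExpressed..A).
#' @slot missingProb per-frame probability that tracking is lost.
#' @slot fps frames per second written to the tracking files.
#' @slot seed master seed.
#' @export
setClass("SimulationConfig",
  representation(nSubjects = "integer", sessionsPerSubject = "integer",
                 framesPerSession = "integer", dwellMean = "numeric",
                 noiseSd = "numeric", offsetSd = "numeric",
                 minExpressed = "integer", missingProb = "numeric",
                 fps = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nSubjects < 1L || object@sessionsPerSubject < 1L ||
        object@framesPerSession < 1L)
      msg <- c(msg, "subject/session/frame counts must be positive")
    if (object@dwellMean < 1) msg <- c(msg, "dwellMean must be >= 1 frame")
    if (object@noiseSd < 0 || object@offsetSd < 0)
      msg <- c(msg, "noise and offset s.d. must be non-negative")
    if (object@missingProb < 0 || object@missingProb > 1)
      msg <- c(msg, "missingProb must lie in [0, 1]")
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SimulationConfig
#'
#' @param nSubjects,sessionsPerSubject,framesPerSession,dwellMean,noiseSd,offsetSd,minExpressed,missingProb,fps,seed
#'   see [SimulationConfig-class].
#' @return A SimulationConfig.
#' @export
#' @examples
#' simulationConfig(nSubjects = 2, framesPerSession = 200, seed = 1)
simulationConfig <- function(nSubjects = 12, sessionsPerSubject = 5,
                             framesPerSession = 4500, dwellMean = 10,
                             noiseSd = 0.5, offsetSd = 1, minExpressed = 8,
                             missingProb = 0.01, fps = 25, seed = 1) {
  new("SimulationConfig", nSubjects = as.integer(nSubjects),
      sessionsPerSubject = as.integer(sessionsPerSubject),
      framesPerSession = as.integer(framesPerSession),
      dwellMean = as.numeric(dwellMean), noiseSd = as.numeric(noiseSd),
      offsetSd = as.numeric(offsetSd), minExpressed = as.integer(minExpressed),
      missingProb = as.numeric(missingProb), fps = as.numeric(fps),
      seed = as.integer(seed))
}
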