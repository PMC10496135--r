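#' @rdname accessors
setMethod("subjectId", "TrackingSession", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "PostureSummary", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "PostureFit", function(x) x@summary@subjectId)
#' @rdname accessors
setMethod("subjectId", "LabeledSession", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "FrequencyTable", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "BoutTable", function(x) x@subjectId)

#' @rdname accessors
setMethod("sessionLabel", "TrackingSession", function(x) x@sessionLabel)
#' @rdname accessors
setMethod("sessionLabel", "LabeledSession", function(x) x@sessionLabel)
#' @rdname accessors
setMethod("sessionLabel", "BoutTable", function(x) x@sessionLabel)

#' @rdname accessors
setMethod("zMatrix", "TrackingSession", function(x) x@z)

#' @rdname accessors
setMethod("fps", "TrackingSession", function(x) x@fps)
#' @rdname accessors
setMethod("fps", "LabeledSession", function(x) x@fps)
#' @rdname accessors
setMethod("fps", "BoutTable", function(x) x@fps)

#' @rdname accessors
setMethod("missingFrames", "TrackingSession", function(x) x@missing)
#' @rdname accessors
setMethod("missingFrames", "DistanceFeatureMatrix", function(x) x@missing)

#' @rdname accessors
setMethod("featureValues", "DistanceFeatureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("frameOrigin", "DistanceFeatureMatrix", function(x) x@origin)

#' @rdname accessors
setMethod("centroids", "PostureSummary", function(x) x@centroids)
#' @rdname accessors
setMethod("centroids", "PostureFit", function(x) x@summary@centroids)

#' @rdname accessors
setMethod("postureCounts", "PostureSummary", function(x) x@counts)
#' @rdname accessors
setMethod("postureCounts", "PostureFit", function(x) x@summary@counts)

#' @rdname accessors
setMethod("postureSummary", "PostureFit", function(x) x@summary)

#' @rdname accessors
setMethod("postureLabels", "PostureFit", function(x) x@labels)
#' @rdname accessors
setMethod("postureLabels", "LabeledSession", function(x) x@posture)

#' @rdname accessors
setMethod("moduleLabels", "LabeledSession", function(x) x@bm)

#' @rdname accessors
setMethod("moduleEntries", "ModuleMap", function(x) x@entries)
#' @rdname accessors
setMethod("moduleCount", "ModuleMap", function(x) x@k)

#' @rdname accessors
setMethod("frequencyCounts", "FrequencyTable", function(x) x@counts)

#' @rdname accessors
setMethod("boutData", "BoutTable", function(x) x@bouts)

#' @rdname accessors
setMethod("archetypeProfiles", "ArchetypeSet", function(x) x@profiles)

setMethod("show", "TrackingSession", function(object) {
  cat("TrackingSession: subject", object@subjectId,
      "| session", object@sessionLabel, "\n")
  cat(" ", nrow(object@z), "frames x 6 hotspots @", object@fps, "fps;",
      sum(object@missing), "missing frame(s)\n")
})

setMethod("show", "CohortLayout", function(object) {
  cat("CohortLayout:", length(object@subjects), "subject(s) under",
      object@root, "\n")
  n <- vapply(object@subjects, length, integer(1))
  cat("  sessions per subject:", paste(unique(n), collapse = ", "), "\n")
})

setMethod("show", "DistanceFeatureMatrix", function(object) {
  cat("DistanceFeatureMatrix:", nrow(object@values),
      "frames x 15 hotspot pairs;", sum(object@missing),
      "missing frame(s)\n")
})

setMethod("show", "PostureSummary", function(object) {
  cat("PostureSummary: subject", object@subjectId, "|",
      nrow(object@centroids), "posture(s)\n")
  if (!anyNA(object@counts))
    cat("  frames per posture:", paste(object@counts, collapse = ", "), "\n")
})

setMethod("show", "PostureFit", function(object) {
  cat("PostureFit: subject", object@summary@subjectId, "| k =", object@k,
      "postures over", length(object@labels), "session(s)\n")
  cat("  explained variance at k:",
      sprintf("%.3f", object@explained[object@k]), "\n")
})

setMethod("show", "ModuleMap", function(object) {
  cat("ModuleMap:", nrow(object@entries), "(subject, posture) pairs ->",
      length(unique(object@entries$bm_id)), "behavioral module(s) (k =",
      object@k, ")\n")
})

setMethod("show", "LabeledSession", function(object) {
  cat("LabeledSession: subject", object@subjectId, "| session",
      object@sessionLabel, "|", length(object@bm), "frames\n")
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable: subject", object@subjectId, "|",
      nrow(object@counts), "module row(s) x", ncol(object@counts),
      "session(s)\n")
})

setMethod("show", "BoutTable", function(object) {
  cat("BoutTable: subject", object@subjectId, "| session",
      object@sessionLabel, "|", nrow(object@bouts), "bout(s) over",
      object@nFrames, "frames @", object@fps, "fps\n")
})

setMethod("show", "ArchetypeSet", function(object) {
  cat("ArchetypeSet:", nrow(object@profiles), "posture archetype(s)\n")
  print(round(object@profiles, 2))
})
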