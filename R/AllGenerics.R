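#' @name accessors
#' @title Accessors for PostureSeg classes
#' @description Slot accessors for the package's S4 containers. Use these
#'   rather than \code{@} access.
#' @param x an object of the documented class.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("missingFrames", function(x) standardGeneric("missingFrames"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("frameOrigin", function(x) standardGeneric("frameOrigin"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("postureCounts", function(x) standardGeneric("postureCounts"))

#' @rdname accessors
#' @export
setGeneric("postureLabels", function(x) standardGeneric("postureLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("postureSummary", function(x) standardGeneric("postureSummary"))

#' @rdname accessors
#' @export
setGeneric("moduleEntries", function(x) standardGeneric("moduleEntries"))

#' @rdname accessors
#' @export
setGeneric("moduleCount", function(x) standardGeneric("moduleCount"))

#' @rdname accessors
#' @export
setGeneric("frequencyCounts", function(x) standardGeneric("frequencyCounts"))

#' @rdname accessors
#' @export
setGeneric("boutData", function(x) standardGeneric("boutData"))

#' @rdname accessors
#' @export
setGeneric("archetypeProfiles", function(x) standardGeneric("archetypeProfiles"))

#' Run-length encode a behavioral-module stream
#'
#' @param x a per-frame integer label stream or a [LabeledSession-class].
#' @param ... further arguments passed to methods.
#' @return A [BoutTable-class].
#' @export
setGeneric("runLengthEncode", function(x, ...) standardGeneric("runLengthEncode"))
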