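## Writers/readers for the pipeline's CSV dialects. All numeric tables are
## headerless comma-separated files (the convention of MATLAB's csvwrite,
## which the field's desktop pipelines emit); the per-subject frequency file
## alone carries a header row so session labels survive a round trip.
## Missing values are written as NaN and read back as NA.

.writePlainCSV <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
              na = "NaN", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.readPlainCSV <- function(path, what = "output") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  read.csv(path, header = FALSE, stringsAsFactors = FALSE,
           na.strings = c("NA", "NaN"))
}

#' Write / read a per-subject mean-distance file
#'
#' The step-1 summary dialect: one row per posture with the animal ID in
#' column 1, the 15 averaged hotspot distances in columns 2-16, and the
#' posture ID in column 17. The conventional file name is
#' \code{Mouse<ID>DistMean.csv}.
#'
#' @param summary a [PostureSummary-class].
#' @param path file path.
#' @return \code{writeMeanDistances} returns the path invisibly;
#'   \code{readMeanDistances} returns a [PostureSummary-class] (frame counts
#'   are not stored in this dialect and come back as NA).
#' @export
writeMeanDistances <- function(summary, path) {
  stopifnot(is(summary, "PostureSummary"))
  cen <- summary@centroids
  dimnames(cen) <- NULL
  df <- data.frame(id = summary@subjectId, cen,
                   posture = seq_len(nrow(cen)))
  .writePlainCSV(df, path)
}

#' @rdname writeMeanDistances
#' @export
readMeanDistances <- function(path) {
  df <- .readPlainCSV(path, "mean-distance")
  if (ncol(df) != 17L)
    stop("mean-distance file must have 17 columns, found ", ncol(df))
  ord <- order(as.integer(df[[17L]]))
  cen <- as.matrix(df[ord, 2:16, drop = FALSE])
  dimnames(cen) <- list(NULL, hotspotPairs())
  new("PostureSummary", subjectId = as.character(df[[1L]][1L]),
      centroids = cen, counts = rep(NA_integer_, nrow(df)))
}

#' Write / read a per-session clustered-frame file
#'
#' The step-1 frame dialect (\code{Clustered<session>.csv}): one row per
#' frame with the animal ID in column 1, the six hotspot z coordinates in
#' columns 2-7, and the posture label in column 8 (0 = missing tracking).
#'
#' @param session a [TrackingSession-class].
#' @param posture integer per-frame posture labels (0 allowed).
#' @param path file path.
#' @return \code{writeClustered} returns the path invisibly;
#'   \code{readClustered} returns a list with \code{subjectId}, \code{z}
#'   (frames x 6), \code{posture}, and \code{sessionLabel}.
#' @export
writeClustered <- function(session, posture, path) {
  stopifnot(is(session, "TrackingSession"),
            length(posture) == nrow(session@z))
  df <- data.frame(id = session@subjectId, session@z,
                   posture = as.integer(posture))
  .writePlainCSV(df, path)
}

#' @rdname writeClustered
#' @param sessionLabel label to attach on read; defaults to the file name
#'   with the "Clustered" prefix stripped.
#' @export
readClustered <- function(path, sessionLabel = NULL) {
  df <- .readPlainCSV(path, "clustered-frame")
  if (ncol(df) != 8L)
    stop("clustered-frame file must have 8 columns, found ", ncol(df))
  if (is.null(sessionLabel))
    sessionLabel <- sub("^Clustered", "",
                        sub("\\.[Cc][Ss][Vv]$", "", basename(path)))
  z <- as.matrix(df[, 2:7])
  colnames(z) <- hotspotNames()
  list(subjectId = as.character(df[[1L]][1L]), z = z,
       posture = as.integer(df[[8L]]), sessionLabel = sessionLabel)
}

#' Write / read the cohort module-assignment file
#'
#' The step-2 dialect (\code{ModulesAssigned.csv}): one row per (subject,
#' posture) pair with its behavioral-module ID in column 3.
#'
#' @param map a [ModuleMap-class].
#' @param path file path.
#' @return \code{writeModulesAssigned} returns the path invisibly;
#'   \code{readModulesAssigned} returns a [ModuleMap-class].
#' @export
writeModulesAssigned <- function(map, path) {
  stopifnot(is(map, "ModuleMap"))
  .writePlainCSV(map@entries, path)
}

#' @rdname writeModulesAssigned
#' @export
readModulesAssigned <- function(path) {
  df <- .readPlainCSV(path, "module-assignment")
  if (ncol(df) != 3L)
    stop("module-assignment file must have 3 columns, found ", ncol(df))
  entries <- data.frame(subject_id = as.character(df[[1L]]),
                        posture_id = as.integer(df[[2L]]),
                        bm_id = as.integer(df[[3L]]),
                        stringsAsFactors = FALSE)
  new("ModuleMap", entries = entries, k = max(entries$bm_id))
}

#' Write / read a per-session module-labeled frame file
#'
#' The step-3 frame dialect (\code{Mouse<ID>_<session>.csv}): identical to
#' the clustered-frame file with an additional column 9 holding the
#' behavioral-module ID of each frame.
#'
#' @param clustered list as returned by [readClustered()].
#' @param bm integer per-frame module labels.
#' @param path file path.
#' @return \code{writeModuleFrames} returns the path invisibly;
#'   \code{readModuleFrames} returns the \code{clustered} list with a
#'   \code{bm} element added.
#' @export
writeModuleFrames <- function(clustered, bm, path) {
  stopifnot(length(bm) == nrow(clustered$z))
  df <- data.frame(id = clustered$subjectId, clustered$z,
                   posture = as.integer(clustered$posture),
                   bm = as.integer(bm))
  .writePlainCSV(df, path)
}

#' @rdname writeModuleFrames
#' @export
readModuleFrames <- function(path) {
  df <- .readPlainCSV(path, "module-frame")
  if (ncol(df) != 9L)
    stop("module-frame file must have 9 columns, found ", ncol(df))
  z <- as.matrix(df[, 2:7])
  colnames(z) <- hotspotNames()
  list(subjectId = as.character(df[[1L]][1L]), z = z,
       posture = as.integer(df[[8L]]), bm = as.integer(df[[9L]]),
       sessionLabel = sub("\\.[Cc][Ss][Vv]$", "", basename(path)))
}

#' Write / read a per-subject frequency file
#'
#' The step-3 summary dialect (\code{FrequenciesMouse<ID>.csv}): one row per
#' behavioral module (a trailing "unassigned" row appears only when frames
#' with missing tracking exist), one column per session, cells counting the
#' frames of that session assigned to that module. A single header row names
#' the sessions.
#'
#' @param freq a [FrequencyTable-class].
#' @param path file path.
#' @return \code{writeFrequencies} returns the path invisibly;
#'   \code{readFrequencies} returns a [FrequencyTable-class].
#' @export
writeFrequencies <- function(freq, path) {
  stopifnot(is(freq, "FrequencyTable"))
  df <- data.frame(bm = rownames(freq@counts), freq@counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("bm", colnames(freq@counts)), collapse = ","), con)
  write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeFrequencies
#' @param subjectId subject to attach on read; defaults to the ID embedded
#'   in the file name.
#' @export
readFrequencies <- function(path, subjectId = NULL) {
  if (!file.exists(path)) stop("frequency file not found: ", path)
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (is.null(subjectId))
    subjectId <- sub("^FrequenciesMouse", "",
                     sub("\\.[Cc][Ss][Vv]$", "", basename(path)))
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(df[[1L]])
  new("FrequencyTable", subjectId = as.character(subjectId), counts = counts)
}
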