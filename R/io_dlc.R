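## Reading DLC-3D tracking CSVs and discovering the mother-folder layout.
## Two header dialects are supported and auto-detected from row 1:
##   * native 3-row header (scorer / bodyparts / coords) with x,y,z triplets
##     per body part and a leading frame-index column;
##   * flat one-row header with one z column per hotspot ("nose_z" or just
##     "nose").
## Only z columns are consumed. Frames with any unparsable/absent z are kept
## (frame alignment matters downstream) but flagged missing.

#' Read a DLC-3D tracking CSV
#'
#' Parses one per-session tracking file into a [TrackingSession-class],
#' keeping only the z coordinate of the six canonical hotspots. Rows whose z
#' is absent or non-numeric for any hotspot are retained in the timeline and
#' flagged in the missingness mask, never dropped.
#'
#' @param path path to the CSV file.
#' @param fps frames per second of the recording (default 25).
#' @param subjectId animal ID; defaults to the name of the containing folder.
#' @param sessionLabel session label; defaults to the file name without
#'   extension.
#' @return A [TrackingSession-class].
#' @export
#' @examples
#' s <- TrackingSession("156", matrix(rnorm(60), ncol = 6))
#' tf <- tempfile(fileext = ".csv")
#' writeTrackingCSV(s, tf)
#' readTrackingCSV(tf, subjectId = "156")
readTrackingCSV <- function(path, fps = 25, subjectId = NULL,
                            sessionLabel = NULL) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  if (file.size(path) == 0) stop("tracking file is empty: ", path)
  if (is.null(subjectId)) subjectId <- basename(dirname(normalizePath(path)))
  if (is.null(sessionLabel))
    sessionLabel <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))

  fields <- count.fields(path, sep = ",", quote = "\"")
  fields <- fields[!is.na(fields)]
  if (length(fields) == 0) stop("tracking file is empty: ", path)
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop("ragged CSV: row ", bad, " of ", path, " has ", fields[bad],
         " fields, expected ", fields[1L])
  }

  firstCell <- tolower(trimws(strsplit(readLines(path, n = 1L), ",")[[1L]][1L]))
  if (identical(firstCell, "scorer")) {
    z <- .readDlc3dNative(path)
  } else {
    z <- .readFlatZ(path)
  }
  TrackingSession(subjectId, z, sessionLabel = sessionLabel, fps = fps)
}

.readDlc3dNative <- function(path) {
  hdr <- read.csv(path, header = FALSE, nrows = 3L,
                  colClasses = "character")
  bodyparts <- .normHotspot(as.character(hdr[2L, ]))
  coords <- tolower(trimws(as.character(hdr[3L, ])))
  zcols <- integer(6L)
  for (h in seq_along(.HOTSPOTS)) {
    hit <- which(bodyparts == .HOTSPOTS[h] & coords == "z")
    if (length(hit) == 0)
      stop("required hotspot column not found: ",
           gsub("_", " ", .HOTSPOTS[h]))
    zcols[h] <- hit[1L]
  }
  dat <- read.csv(path, header = FALSE, skip = 3L,
                  colClasses = "character")
  if (nrow(dat) == 0) stop("tracking file has no data rows: ", path)
  z <- vapply(zcols, function(j) suppressWarnings(as.numeric(dat[[j]])),
              numeric(nrow(dat)))
  matrix(z, ncol = 6L)
}

.readFlatZ <- function(path) {
  dat <- read.csv(path, header = TRUE, colClasses = "character",
                  check.names = FALSE)
  if (nrow(dat) == 0) stop("tracking file has no data rows: ", path)
  nm <- .normHotspot(names(dat))
  zcols <- integer(6L)
  for (h in seq_along(.HOTSPOTS)) {
    hit <- which(nm == .HOTSPOTS[h] | nm == paste0(.HOTSPOTS[h], "_z"))
    if (length(hit) == 0)
      stop("required hotspot column not found: ",
           gsub("_", " ", .HOTSPOTS[h]))
    zcols[h] <- hit[1L]
  }
  z <- vapply(zcols, function(j) suppressWarnings(as.numeric(dat[[j]])),
              numeric(nrow(dat)))
  matrix(z, ncol = 6L)
}

#' Write a tracking session in the native DLC-3D dialect
#'
#' Emits the 3-row scorer/bodyparts/coords header with x,y,z triplets per
#' hotspot (x and y are zero-filled: only z is meaningful here) and a leading
#' 0-based frame-index column. Missing z values are written as NaN.
#' \code{readTrackingCSV()} round-trips the z matrix exactly.
#'
#' @param session a [TrackingSession-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTrackingCSV <- function(session, path) {
  stopifnot(is(session, "TrackingSession"))
  z <- session@z
  n <- nrow(z)
  hdr1 <- c("scorer", rep("DLC_3D", 18L))
  hdr2 <- c("bodyparts", rep(hotspotNames(), each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "z"), times = 6L))
  body <- matrix(0, nrow = n, ncol = 18L)
  body[, seq(3L, 18L, by = 3L)] <- z
  df <- data.frame(idx = seq_len(n) - 1L, body, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
              na = "NaN")
  invisible(path)
}

## Output artifacts of the pipeline itself, skipped when re-scanning a mother
## folder that has already been processed.
.RESERVED_DIRS <- c("Mean Distances", "Modules")
.RESERVED_FILE_RE <- "^(Clustered|Mouse|Frequencies)"

#' Discover the cohort layout of a mother folder
#'
#' Scans the mother folder for one subfolder per animal ID, each containing
#' that animal's per-session tracking CSVs. Session files are ordered by a
#' deterministic natural sort (digit runs zero-padded, then lexicographic) so
#' session order is stable across platforms. Files whose name does not
#' contain the folder's ID, and non-CSV files, are excluded with a warning.
#' Folders holding pipeline outputs ("Mean Distances", "Modules") and files
#' written by the pipeline are ignored.
#'
#' @param root path of the mother folder.
#' @return A [CohortLayout-class].
#' @export
discoverLayout <- function(root) {
  if (!dir.exists(root)) stop("mother folder does not exist: ", root)
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[!(basename(dirs) %in% .RESERVED_DIRS)]
  if (length(dirs) == 0)
    stop("no subject subfolders found in mother folder: ", root)

  subjects <- list()
  for (d in dirs) {
    id <- basename(d)
    files <- list.files(d, full.names = TRUE)
    files <- files[!file.info(files)$isdir]
    files <- files[!grepl(.RESERVED_FILE_RE, basename(files))]
    keep <- logical(length(files))
    for (i in seq_along(files)) {
      fn <- basename(files[i])
      if (!grepl("\\.[Cc][Ss][Vv]$", fn)) {
        warning("excluding non-CSV file from subject ", id, ": ", fn)
      } else if (!grepl(id, fn, fixed = TRUE)) {
        warning("excluding file whose name lacks subject ID ", id, ": ", fn)
      } else keep[i] <- TRUE
    }
    files <- files[keep]
    if (length(files) == 0) {
      warning("subject folder ", id, " contains no usable tracking files")
      next
    }
    subjects[[id]] <- files[naturalOrder(basename(files))]
  }
  if (length(subjects) == 0)
    stop("no subjects with tracking files found in: ", root)
  new("CohortLayout", root = root, subjects = subjects)
}

#' Validate frame-count agreement across a cohort
#'
#' Multi-session experiments require every subject's k-th session file to
#' contain the same number of frames. Returns a report rather than erroring,
#' listing every (subject, session, frames) triple that deviates from the
#' modal frame count of its session ordinal.
#'
#' @param layout a [CohortLayout-class].
#' @param sessions named list (by subject ID) of lists of
#'   [TrackingSession-class] objects, in the layout's session order.
#' @return A list with elements \code{pass} (logical) and \code{mismatches}
#'   (data.frame with columns subject, session, frames, expected).
#' @export
validateFrameCounts <- function(layout, sessions) {
  stopifnot(is(layout, "CohortLayout"))
  ids <- names(layout@subjects)
  if (!all(ids %in% names(sessions)))
    stop("sessions missing for subject(s): ",
         paste(setdiff(ids, names(sessions)), collapse = ", "))
  nSess <- vapply(sessions[ids], length, integer(1))
  mism <- data.frame(subject = character(), session = character(),
                     frames = integer(), expected = integer(),
                     stringsAsFactors = FALSE)
  for (ord in seq_len(max(nSess))) {
    have <- ids[nSess >= ord]
    counts <- vapply(have, function(id) nrow(sessions[[id]][[ord]]@z),
                     integer(1))
    tab <- table(counts)
    expected <- as.integer(names(tab)[which.max(tab)])
    off <- which(counts != expected)
    for (i in off) {
      mism <- rbind(mism, data.frame(
        subject = have[i],
        session = sessions[[have[i]]][[ord]]@sessionLabel,
        frames = counts[[i]], expected = expected,
        stringsAsFactors = FALSE))
    }
  }
  list(pass = nrow(mism) == 0L, mismatches = mism)
}

#' Read all sessions of a cohort
#'
#' Convenience loader: applies [readTrackingCSV()] to every file of a
#' [CohortLayout-class]. Session labels are the file names with the subject
#' ID and separators stripped, so labels align across subjects
#' ("156_s01.csv" becomes "s01").
#'
#' @param layout a [CohortLayout-class].
#' @param fps frames per second.
#' @return Named list (by subject) of lists of [TrackingSession-class].
#' @export
readCohortSessions <- function(layout, fps = 25) {
  stopifnot(is(layout, "CohortLayout"))
  out <- lapply(names(layout@subjects), function(id) {
    lapply(layout@subjects[[id]], function(p) {
      readTrackingCSV(p, fps = fps, subjectId = id,
                      sessionLabel = .sessionLabelFromFile(p, id))
    })
  })
  names(out) <- names(layout@subjects)
  out
}

.sessionLabelFromFile <- function(path, id) {
  base <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  lab <- gsub(id, "", base, fixed = TRUE)
  lab <- gsub("^[._-]+|[._-]+$", "", lab)
  if (nzchar(lab)) lab else base
}
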