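## Step 3: relabel every frame with its behavioral module and tally
## per-session frequency tables.

#' Assign behavioral modules to per-frame posture labels
#'
#' Translates a session's posture labels into module labels through a
#' [ModuleMap-class]. Frame order and count are preserved; the sentinel 0
#' (missing tracking) propagates unchanged. A posture ID absent from the map
#' is an error naming the subject and posture.
#'
#' @param posture integer per-frame posture labels (0 = unassigned).
#' @param map a [ModuleMap-class].
#' @param subjectId subject the labels belong to.
#' @param sessionLabel session label.
#' @param fps frames per second.
#' @return A [LabeledSession-class].
#' @export
#' @examples
#' m <- new("ModuleMap",
#'          entries = data.frame(subject_id = "a", posture_id = 1:2,
#'                               bm_id = c(2L, 1L)),
#'          k = 2L)
#' moduleLabels(assignModules(c(1L, 1L, 2L), m, "a", "s1"))
assignModules <- function(posture, map, subjectId, sessionLabel = "session",
                          fps = 25) {
  stopifnot(is(map, "ModuleMap"))
  posture <- as.integer(posture)
  ent <- map@entries[map@entries$subject_id == subjectId, , drop = FALSE]
  lut <- integer(max(c(ent$posture_id, 1L)))
  lut[ent$posture_id] <- ent$bm_id
  used <- unique(posture[posture > 0L])
  absent <- used[used > length(lut) | lut[pmin(used, length(lut))] == 0L]
  if (length(absent))
    stop("posture(s) missing from module map for subject ", subjectId, ": ",
         paste(sort(absent), collapse = ", "))
  bm <- integer(length(posture))
  bm[posture > 0L] <- lut[posture[posture > 0L]]
  new("LabeledSession", subjectId = as.character(subjectId),
      sessionLabel = as.character(sessionLabel), posture = posture,
      bm = as.integer(bm), fps = as.numeric(fps))
}

#' Count frames per behavioral module and session
#'
#' Builds the per-subject frequency table: rows are behavioral modules 1..k,
#' columns the sessions in the order given; cell (b, s) is the number of
#' frames of session s labeled with module b. A trailing "unassigned" row is
#' appended only when frames with missing tracking exist, so every column
#' sums to its session's frame count.
#'
#' @param labeled list of [LabeledSession-class] for one subject.
#' @param k total number of behavioral modules (defaults to the largest
#'   label observed).
#' @return A [FrequencyTable-class].
#' @export
countFrequencies <- function(labeled, k = NULL) {
  stopifnot(length(labeled) >= 1L)
  ids <- unique(vapply(labeled, function(s) s@subjectId, character(1)))
  if (length(ids) != 1L)
    stop("labeled sessions belong to different subjects: ",
         paste(ids, collapse = ", "))
  if (is.null(k))
    k <- max(1L, max(vapply(labeled, function(s) max(c(s@bm, 0L)),
                            integer(1))))
  counts <- vapply(labeled, function(s) tabulate(s@bm, nbins = k),
                   integer(k))
  counts <- matrix(counts, nrow = k,
                   dimnames = list(as.character(seq_len(k)),
                                   vapply(labeled, function(s) s@sessionLabel,
                                          character(1))))
  unass <- vapply(labeled, function(s) sum(s@bm == 0L), integer(1))
  if (any(unass > 0L))
    counts <- rbind(counts, unassigned = unass)
  new("FrequencyTable", subjectId = ids, counts = counts)
}
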