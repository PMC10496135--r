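## Bout (behavioral-sequence) analytics: run-length encoding of the
## per-frame module stream, frame-to-millisecond conversion, the short-bout
## percentage, and bout-duration distributions. Bouts never span session
## boundaries: each session's stream is encoded on its own.

#' @rdname runLengthEncode
#' @param subjectId,sessionLabel identity attached to the bout table when
#'   encoding a bare label vector.
#' @param fps frames per second.
#' @export
#' @examples
#' boutData(runLengthEncode(c(1L, 1L, 2L, 2L, 2L, 1L)))
setMethod("runLengthEncode", "integer",
  function(x, subjectId = "subject", sessionLabel = "session", fps = 25) {
    if (length(x) == 0) stop("label stream is empty")
    r <- rle(x)
    len <- as.integer(r$lengths)
    bouts <- data.frame(bm_id = as.integer(r$values),
                        start = c(1L, cumsum(len)[-length(len)] + 1L),
                        length = len)
    new("BoutTable", subjectId = as.character(subjectId),
        sessionLabel = as.character(sessionLabel), bouts = bouts,
        fps = as.numeric(fps), nFrames = length(x))
  })

#' @rdname runLengthEncode
#' @export
setMethod("runLengthEncode", "numeric",
  function(x, subjectId = "subject", sessionLabel = "session", fps = 25) {
    runLengthEncode(as.integer(x), subjectId = subjectId,
                    sessionLabel = sessionLabel, fps = fps)
  })

#' @rdname runLengthEncode
#' @export
setMethod("runLengthEncode", "LabeledSession", function(x, ...) {
  runLengthEncode(x@bm, subjectId = x@subjectId,
                  sessionLabel = x@sessionLabel, fps = x@fps)
})

#' Convert a frame count to a duration in milliseconds
#'
#' At 25 fps each frame captures 40 ms of action, so 3 frames are 120 ms and
#' an 806-frame bout lasts about 32 s.
#'
#' @param nFrames number of frames (>= 0).
#' @param fps frames per second (> 0).
#' @return Duration in milliseconds.
#' @export
#' @examples
#' framesToDuration(3, 25)    # 120
#' framesToDuration(806, 25)  # 32240
framesToDuration <- function(nFrames, fps = 25) {
  if (length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a positive number")
  if (any(nFrames < 0)) stop("frame counts must be non-negative")
  nFrames * 1000 / fps
}

#' Percentage of time spent in short bouts
#'
#' The fraction of frames, in percent, that belong to bouts shorter than
#' \code{thresholdFrames}: (frames in 1-frame bouts + frames in 2-frame
#' bouts) x 100 / total frames for the default threshold of 3. Sentinel
#' (module 0) bouts are excluded from both numerator and denominator unless
#' \code{includeUnassigned}.
#'
#' @param bouts a [BoutTable-class] or list of them.
#' @param thresholdFrames bouts with fewer frames than this count as short
#'   (default 3).
#' @param includeUnassigned keep sentinel bouts in the computation.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' bt <- runLengthEncode(c(1L, 1L, 2L, 1L, 1L, 3L, 3L, 3L))
#' shortBoutPercentage(bt)  # 62.5
shortBoutPercentage <- function(bouts, thresholdFrames = 3,
                                includeUnassigned = FALSE) {
  if (thresholdFrames < 1) stop("thresholdFrames must be >= 1")
  b <- .pooledBouts(bouts, includeUnassigned)
  total <- sum(b$length)
  if (total <= 0) stop("no frames to evaluate")
  sum(b$length[b$length < thresholdFrames]) * 100 / total
}

#' Bout-duration distribution
#'
#' Tabulates bout lengths, their cumulative frequencies (fraction of bouts
#' of length <= L for each observed L), and the median bout length (over
#' bouts, not frames). With \code{perBm} the statistics are stratified by
#' behavioral module.
#'
#' @param bouts a [BoutTable-class] or list of them.
#' @param perBm stratify by behavioral module.
#' @param includeUnassigned keep sentinel (module 0) bouts.
#' @return A list with \code{distribution} (data.frame with columns
#'   \code{bm} (only when \code{perBm}), \code{length}, \code{count},
#'   \code{cum_fraction}) and \code{medians} (data.frame with \code{bm},
#'   \code{median_frames}).
#' @export
#' @examples
#' bt <- runLengthEncode(c(1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L))
#' durationDistribution(bt)$medians
durationDistribution <- function(bouts, perBm = FALSE,
                                 includeUnassigned = FALSE) {
  b <- .pooledBouts(bouts, includeUnassigned)
  if (nrow(b) == 0) stop("no bouts to summarize")
  strata <- if (perBm) split(b$length, b$bm_id) else list(all = b$length)
  dist <- do.call(rbind, lapply(names(strata), function(g) {
    len <- strata[[g]]
    tab <- table(len)
    L <- as.integer(names(tab))
    cnt <- as.integer(tab)
    df <- data.frame(length = L, count = cnt,
                     cum_fraction = cumsum(cnt) / sum(cnt))
    if (perBm) cbind(bm = as.integer(g), df) else df
  }))
  med <- data.frame(bm = if (perBm) as.integer(names(strata)) else NA_integer_,
                    median_frames = vapply(strata, function(v)
                      as.numeric(median(v)), numeric(1)))
  rownames(med) <- NULL
  list(distribution = dist, medians = med)
}

.pooledBouts <- function(bouts, includeUnassigned) {
  if (is(bouts, "BoutTable")) bouts <- list(bouts)
  stopifnot(all(vapply(bouts, is, logical(1), "BoutTable")))
  b <- do.call(rbind, lapply(bouts, function(bt) bt@bouts))
  if (!includeUnassigned) b <- b[b$bm_id != 0L, , drop = FALSE]
  b
}
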