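## Session-normalization scores for stimulus-evoked change and the
## correlation surface between module expression and a manually scored
## ethogram.

#' Normalized change in module expression relative to a reference session
#'
#' For each behavioral module and each non-reference session, computes
#' (a - b) / (a + b), where a is the module's frame count in the test
#' session and b its count in the reference session (habituation for
#' time-driven change, SHAM for whisker-dependent change). The score lies in
#' [-1, 1]; when a = b = 0 it is defined as 0 so downstream heatmaps stay
#' finite. Multiply by 100 to present as percent change.
#'
#' @param freq a [FrequencyTable-class] for one subject.
#' @param reference session label of the reference column.
#' @return data.frame with columns \code{subject_id}, \code{bm_id},
#'   \code{session_label}, \code{value}.
#' @export
#' @examples
#' ft <- new("FrequencyTable", subjectId = "156",
#'           counts = matrix(c(100L, 50L, 300L, 50L), nrow = 2,
#'                           dimnames = list(c("1", "2"), c("hab", "t1"))))
#' normalizeSessions(ft, "hab")
normalizeSessions <- function(freq, reference) {
  stopifnot(is(freq, "FrequencyTable"))
  counts <- freq@counts
  counts <- counts[rownames(counts) != "unassigned", , drop = FALSE]
  if (!(reference %in% colnames(counts)))
    stop("reference session not present: ", reference, " (have: ",
         paste(colnames(counts), collapse = ", "), ")")
  b <- counts[, reference]
  test <- setdiff(colnames(counts), reference)
  out <- do.call(rbind, lapply(test, function(s) {
    a <- counts[, s]
    denom <- a + b
    val <- ifelse(denom == 0, 0, (a - b) / ifelse(denom == 0, 1, denom))
    data.frame(subject_id = freq@subjectId,
               bm_id = as.integer(rownames(counts)),
               session_label = s, value = as.numeric(val),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlate module expression with a manual ethogram
#'
#' Pearson product-moment correlation, across subjects, between the time
#' spent in each behavioral module and the time spent in each manually
#' scored category (e.g. active/passive avoidance, aided/unaided rearing).
#' Time may be given in frames or seconds; at a fixed frame rate the two are
#' proportional and yield identical r. Constant vectors produce a flagged
#' undefined entry (NA with \code{constant} TRUE), never a silent 0.
#'
#' @param freqs list of [FrequencyTable-class], one per subject.
#' @param ethogram data.frame with columns \code{subject_id},
#'   \code{category}, \code{time}.
#' @param sessions optional character vector restricting which sessions
#'   contribute to the module time; default all.
#' @return A list with matrices \code{r}, \code{p} (two-sided,
#'   t-distribution), \code{constant} (logical), and scalar \code{n}
#'   (paired subjects). Rows are modules, columns ethogram categories.
#' @export
correlateBmEthogram <- function(freqs, ethogram, sessions = NULL) {
  stopifnot(all(c("subject_id", "category", "time") %in% names(ethogram)))
  if (any(ethogram$time < 0)) stop("ethogram times must be non-negative")
  bmTime <- .moduleTimeMatrix(freqs, sessions)

  ethoIds <- unique(as.character(ethogram$subject_id))
  unmatched <- c(setdiff(rownames(bmTime), ethoIds),
                 setdiff(ethoIds, rownames(bmTime)))
  if (length(unmatched))
    stop("subject IDs not matched between module tables and ethogram: ",
         paste(sort(unique(unmatched)), collapse = ", "))
  n <- nrow(bmTime)
  if (n < 3L)
    stop("at least 3 paired subjects are required, found ", n)

  cats <- unique(as.character(ethogram$category))
  etho <- matrix(0, nrow = n, ncol = length(cats),
                 dimnames = list(rownames(bmTime), cats))
  for (i in seq_len(nrow(ethogram)))
    etho[as.character(ethogram$subject_id[i]),
         as.character(ethogram$category[i])] <- ethogram$time[i]

  bms <- colnames(bmTime)
  r <- p <- matrix(NA_real_, nrow = length(bms), ncol = length(cats),
                   dimnames = list(bms, cats))
  const <- matrix(FALSE, nrow = length(bms), ncol = length(cats),
                  dimnames = list(bms, cats))
  for (b in seq_along(bms)) {
    for (cc in seq_along(cats)) {
      x <- bmTime[, b]; y <- etho[, cc]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        const[b, cc] <- TRUE
      } else {
        ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
        r[b, cc] <- unname(ct$estimate)
        p[b, cc] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, constant = const, n = n)
}

## subjects x modules matrix of frames summed over the chosen sessions
.moduleTimeMatrix <- function(freqs, sessions = NULL) {
  stopifnot(length(freqs) >= 1L,
            all(vapply(freqs, is, logical(1), "FrequencyTable")))
  bmRows <- lapply(freqs, function(f)
    rownames(f@counts)[rownames(f@counts) != "unassigned"])
  bms <- bmRows[[1L]]
  if (!all(vapply(bmRows, function(x) identical(x, bms), logical(1))))
    stop("frequency tables disagree on behavioral-module rows")
  mat <- t(vapply(freqs, function(f) {
    counts <- f@counts[bms, , drop = FALSE]
    if (!is.null(sessions)) {
      miss <- setdiff(sessions, colnames(counts))
      if (length(miss))
        stop("session(s) absent from frequency table of subject ",
             f@subjectId, ": ", paste(miss, collapse = ", "))
      counts <- counts[, sessions, drop = FALSE]
    }
    rowSums(counts)
  }, numeric(length(bms))))
  rownames(mat) <- vapply(freqs, function(f) f@subjectId, character(1))
  colnames(mat) <- bms
  mat
}
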