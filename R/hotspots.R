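## Canonical hotspot order. Every module indexes body parts through these two
## helpers; nothing else hard-codes the order.

.HOTSPOTS <- c("nose", "eyes", "neck", "mid_back", "lower_back",
               "tail_attachment")

.PAIRS <- t(utils::combn(6L, 2L))  # 15 x 2, i < j, canonical enumeration

#' Canonical bodily hotspots
#'
#' The six tracked body parts whose vertical (z) position encodes posture, in
#' the fixed order used by every function in the package: nose, eyes, neck,
#' mid back, lower back, tail attachment.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' hotspotNames()
hotspotNames <- function() .HOTSPOTS

#' Canonical hotspot pairs
#'
#' The 15 unordered hotspot pairs (i < j in canonical order) defining the
#' columns of the pairwise height-difference feature matrix.
#'
#' @param asMatrix return the 15 x 2 index matrix instead of pair labels.
#' @return Character vector of 15 pair labels, or an integer matrix.
#' @export
hotspotPairs <- function(asMatrix = FALSE) {
  if (asMatrix) return(.PAIRS)
  paste(.HOTSPOTS[.PAIRS[, 1L]], .HOTSPOTS[.PAIRS[, 2L]], sep = "-")
}

## lower-case, collapse runs of non-alphanumerics to "_": "Mid Back" ->
## "mid_back", so DLC bodypart labels with spaces or dots match.
.normHotspot <- function(x) {
  x <- gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  gsub("^_|_$", "", x)
}
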