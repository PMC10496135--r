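## Folder-level runners chaining the three pipeline steps over a mother
## folder, reading and writing the conventional file dialects.

#' Run posture extraction over a mother folder
#'
#' Step 1 for every subject folder: loads the session tracking files,
#' extracts postures with [extractPostures()], writes the per-session
#' clustered-frame files and the subject's mean-distance file into the
#' subject folder, and copies the latter into "Mean Distances" under the
#' mother folder.
#'
#' @param mother path of the mother folder.
#' @param config a [ClusteringConfig-class]. Each subject is clustered with
#'   a seed offset by its position so subjects are independent but the whole
#'   run is reproducible.
#' @param fps frames per second of the recordings.
#' @param absolute cluster absolute rather than signed differences.
#' @return Named list of [PostureFit-class], one per subject, invisibly.
#' @export
runPostureExtraction <- function(mother, config = clusteringConfig(),
                                 fps = 25, absolute = FALSE) {
  layout <- discoverLayout(mother)
  sessions <- readCohortSessions(layout, fps = fps)
  chk <- validateFrameCounts(layout, sessions)
  if (!chk$pass)
    warning("frame counts differ across subjects; offending sessions: ",
            paste(chk$mismatches$subject, chk$mismatches$session,
                  collapse = ", "))
  fits <- list()
  for (i in seq_along(sessions)) {
    id <- names(sessions)[i]
    cfg <- clusteringConfig(kMax = config@kMax,
                            varianceCutoff = config@varianceCutoff,
                            replicates = config@replicates,
                            seed = config@seed + i - 1L,
                            maxIter = config@maxIter)
    fits[[id]] <- extractPostures(sessions[[id]], cfg, absolute = absolute,
                                  outDir = file.path(mother, id),
                                  meanDistDir = file.path(mother,
                                                          "Mean Distances"))
  }
  invisible(fits)
}

#' Run cross-subject module matching over a mother folder
#'
#' Step 2: loads every subject's mean-distance file from "Mean Distances",
#' recovers posture frame counts from the clustered-frame files, clusters
#' the pooled centroids with [matchPostures()], and writes
#' ModulesAssigned.csv into the mother folder.
#'
#' @param mother path of the mother folder.
#' @param k number of behavioral modules; \code{NULL} applies the
#'   k = MIN(poses) + 1 recommendation ([recommendK()]).
#' @param config a [ClusteringConfig-class].
#' @param weighted weight centroids by posture frame counts.
#' @return The [ModuleMap-class], invisibly.
#' @export
runModuleMatching <- function(mother, k = NULL, config = clusteringConfig(),
                              weighted = FALSE) {
  mdDir <- file.path(mother, "Mean Distances")
  files <- list.files(mdDir, pattern = "^Mouse.*DistMean\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0)
    stop("no mean-distance files found under ", mdDir,
         "; run posture extraction first")
  files <- files[naturalOrder(basename(files))]
  summaries <- lapply(files, readMeanDistances)

  ## posture frame counts live in the clustered-frame files
  for (i in seq_along(summaries)) {
    id <- summaries[[i]]@subjectId
    cl <- list.files(file.path(mother, id), pattern = "^Clustered.*\\.csv$",
                     full.names = TRUE)
    if (length(cl)) {
      lab <- unlist(lapply(cl, function(p) readClustered(p)$posture))
      summaries[[i]]@counts <- tabulate(lab[lab > 0L],
                                        nbins = nrow(summaries[[i]]@centroids))
    }
  }

  if (is.null(k))
    k <- recommendK(vapply(summaries, function(s) nrow(s@centroids),
                           integer(1)))
  map <- matchPostures(summaries, k, config, weighted = weighted)
  writeModulesAssigned(map, file.path(mother, "ModulesAssigned.csv"))
  invisible(map)
}

#' Run frame labeling over a mother folder
#'
#' Step 3: reads each subject's clustered-frame files and the cohort module
#' map, relabels every frame with its behavioral module, writes the
#' per-session module-frame files into each subject's "Modules" folder and
#' the per-subject frequency file into the subject folder.
#'
#' @param mother path of the mother folder.
#' @param map a [ModuleMap-class]; \code{NULL} reads ModulesAssigned.csv
#'   from the mother folder.
#' @param fps frames per second.
#' @return Named list of [FrequencyTable-class], one per subject, invisibly.
#' @export
runModuleAssignment <- function(mother, map = NULL, fps = 25) {
  if (is.null(map))
    map <- readModulesAssigned(file.path(mother, "ModulesAssigned.csv"))
  ids <- unique(map@entries$subject_id)
  out <- list()
  for (id in ids) {
    subjDir <- file.path(mother, id)
    cl <- list.files(subjDir, pattern = "^Clustered.*\\.csv$",
                     full.names = TRUE)
    if (length(cl) == 0)
      stop("no clustered-frame files for subject ", id, " under ", subjDir)
    cl <- cl[naturalOrder(basename(cl))]
    modDir <- file.path(subjDir, "Modules")
    dir.create(modDir, recursive = TRUE, showWarnings = FALSE)
    labeled <- lapply(cl, function(p) {
      cf <- readClustered(p)
      sess <- .sessionLabelFromFile(sub("^Clustered", "", basename(p)), id)
      ls <- assignModules(cf$posture, map, id, sessionLabel = sess,
                          fps = fps)
      writeModuleFrames(cf, ls@bm,
                        file.path(modDir, paste0("Mouse", id, "_", sess,
                                                 ".csv")))
      ls
    })
    freq <- countFrequencies(labeled, k = map@k)
    writeFrequencies(freq, file.path(subjDir,
                                     paste0("FrequenciesMouse", id, ".csv")))
    out[[id]] <- freq
  }
  invisible(out)
}

#' Run the full three-step pipeline
#'
#' Convenience wrapper: posture extraction, module matching, frame labeling.
#'
#' @param mother path of the mother folder.
#' @param config a [ClusteringConfig-class].
#' @param k module count for step 2; \code{NULL} for the MIN+1 rule.
#' @param fps frames per second.
#' @return List with \code{fits}, \code{map}, and \code{frequencies}.
#' @export
runPipeline <- function(mother, config = clusteringConfig(), k = NULL,
                        fps = 25) {
  fits <- runPostureExtraction(mother, config, fps = fps)
  map <- runModuleMatching(mother, k = k, config = config)
  freqs <- runModuleAssignment(mother, map = map, fps = fps)
  list(fits = fits, map = map, frequencies = freqs)
}
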