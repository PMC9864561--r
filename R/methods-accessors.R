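#' Accessors for mvpafusion objects
#'
#' Small, uniform accessor set: \code{dataArray} returns the numeric array
#' of a container, \code{timePoints} the ms grid, \code{categoryLabels} /
#' \code{depictionLabels} the per-trial labels, \code{conditionIds} the
#' condition names, \code{rdmValues} the dissimilarity matrix,
#' \code{accuracyValues} the accuracy vector/matrix/map,
#' \code{pValues}/\code{clusters} the inferential results,
#' \code{peakLatency}/\code{peakCI} bootstrap peak summaries.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("dataArray", "EpochSet", function(object) object@data)
#' @rdname accessors
setMethod("dataArray", "SupertrialSet", function(object) object@data)
#' @rdname accessors
setMethod("dataArray", "BetaSet", function(object) object@betas)

#' @rdname accessors
setMethod("timePoints", "EpochSet", function(object) object@times)
#' @rdname accessors
setMethod("timePoints", "SupertrialSet", function(object) object@times)
#' @rdname accessors
setMethod("timePoints", "TimeCourse", function(object) object@times)
#' @rdname accessors
setMethod("timePoints", "TGMatrix", function(object) object@times)
#' @rdname accessors
setMethod("timePoints", "FusionTimeCourse", function(object) object@times)

#' @rdname accessors
setMethod("categoryLabels", "EpochSet", function(object) object@category)
#' @rdname accessors
setMethod("categoryLabels", "SupertrialSet",
          function(object) object@category)

#' @rdname accessors
setMethod("depictionLabels", "EpochSet", function(object) object@depiction)

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(object) object@srate)
#' @rdname accessors
setMethod("samplingRate", "GazeEpoch", function(object) object@srate)

#' @rdname accessors
setMethod("conditionIds", "RDM", function(object) object@conditionIds)
#' @rdname accessors
setMethod("conditionIds", "GLMFit", function(object) object@conditionIds)

#' @rdname accessors
setMethod("rdmValues", "RDM", function(object) object@values)

#' @rdname accessors
setMethod("accuracyValues", "TimeCourse", function(object) object@values)
#' @rdname accessors
setMethod("accuracyValues", "TGMatrix", function(object) object@values)
#' @rdname accessors
setMethod("accuracyValues", "AccuracyMap", function(object) object@values)
#' @rdname accessors
setMethod("accuracyValues", "FusionTimeCourse",
          function(object) object@values)

#' @rdname accessors
setMethod("chanceLevel", "TimeCourse", function(object) object@chance)

#' @rdname accessors
setMethod("pValues", "PermTestResult", function(object) object@pValues)
#' @rdname accessors
setMethod("pValues", "ClusterResult", function(object) object@clusterP)

#' @rdname accessors
setMethod("clusters", "ClusterResult", function(object) object@clusters)

#' @rdname accessors
setMethod("voxelCoords", "BetaSet", function(object) object@voxelCoords)

#' @rdname accessors
setMethod("peakLatency", "PeakCI", function(object) object@peakLatency)
#' @rdname accessors
setMethod("peakCI", "PeakCI",
          function(object) c(low = object@ciLow, high = object@ciHigh))

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3],
      "time points\n")
  cat("  time:", min(object@times), "..", max(object@times), "ms at",
      object@srate, "Hz\n")
  cat("  categories:", length(unique(object@category)),
      "| depictions:", paste(unique(object@depiction), collapse = ", "),
      "\n")
})

setMethod("show", "BetaSet", function(object) {
  d <- dim(object@betas)
  cat("BetaSet [", object@roiLabel, "]: ", d[1], " runs x ", d[2],
      " conditions x ", d[3], " voxels\n", sep = "")
  if (!anyNA(object@dims))
    cat("  grid:", paste(object@dims, collapse = " x "), "\n")
})

setMethod("show", "RDM", function(object) {
  n <- nrow(object@values)
  cat("RDM:", n, "x", n, "(1 - Pearson r)\n")
  lt <- lowerTriangle(object)
  cat("  lower triangle: mean", round(mean(lt), 3), "range [",
      round(min(lt), 3), ",", round(max(lt), 3), "]\n")
})

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse (", object@metric, "): ", length(object@values),
      " time points, ", min(object@times), "..", max(object@times),
      " ms\n", sep = "")
  i <- which.max(object@values)
  cat("  peak ", round(object@values[i], 2), " at ", object@times[i],
      " ms", if (!is.na(object@chance))
        paste0(" (chance ", object@chance, ")"), "\n", sep = "")
})

setMethod("show", "TGMatrix", function(object) {
  cat("TGMatrix:", nrow(object@values), "x", ncol(object@values),
      "train x test accuracies (%)\n")
})

setMethod("show", "AccuracyMap", function(object) {
  cat("AccuracyMap:", paste(dim(object@values), collapse = " x "),
      "grid,", sum(object@mask), "in-mask voxels\n")
  v <- object@values[object@mask]
  cat("  accuracy: mean", round(mean(v, na.rm = TRUE), 2), "max",
      round(max(v, na.rm = TRUE), 2), "%\n")
})

setMethod("show", "FusionTimeCourse", function(object) {
  cat("FusionTimeCourse [", object@roi, "]: ", length(object@values),
      " time points\n", sep = "")
  i <- which.max(object@values)
  cat("  peak r =", round(object@values[i], 3), "at", object@times[i],
      "ms\n")
})

setMethod("show", "PermTestResult", function(object) {
  cat("PermTestResult:", length(object@pValues), "points,",
      object@nPermutations, "permutations,", object@tail, "-tailed\n")
  cat("  min p:", format(min(object@pValues)), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@clusters), "suprathreshold",
      "cluster(s),", sum(object@significant), "significant at alpha =",
      object@alpha, "\n")
})

setMethod("show", "PeakCI", function(object) {
  cat("PeakCI: peak ", object@peakLatency, " ms, 95% CI [",
      round(object@ciLow, 2), ", ", round(object@ciHigh, 2), "] ms (",
      object@nBoot, " bootstrap samples)\n", sep = "")
})

setMethod("show", "GLMFit", function(object) {
  cat("GLMFit:", nrow(object@betas), "conditions x", ncol(object@betas),
      "voxels;", ncol(object@meanResidual), "candidate HRFs\n")
  cat("  chosen HRF indices:",
      paste(sort(unique(object@chosenHrfIndex)), collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  p <- object@patterns[[1]]
  cat("GroundTruth:", nrow(p), "categories x", ncol(p), "features,",
      length(object@patterns), "depictions, sharedFraction =",
      object@sharedFraction, "\n")
})

setMethod("show", "GazeEpoch", function(object) {
  cat("GazeEpoch:", length(object@x), "samples at", object@srate, "Hz,",
      nrow(object@plantedSaccades), "planted saccade(s)\n")
})
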