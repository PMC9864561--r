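#' @import methods
NULL

# Depiction levels are fixed by the experimental design: three renderings of
# the same object categories at increasing visual abstraction.
DEPICTION_LEVELS <- c("photo", "drawing", "sketch")

#' GroundTruth: latent category patterns underlying the synthetic data
#'
#' Holds the per-depiction category pattern matrices, the fraction of
#' pattern variance shared between depiction types, the evoked response
#' profile, and the noise level used by the simulators. The per-depiction
#' pattern for a category is
#' \code{sqrt(sharedFraction) * common + sqrt(1 - sharedFraction) * specific},
#' so the expected between-depiction pattern correlation equals
#' \code{sharedFraction}.
#'
#' @slot patterns named list (one element per depiction) of
#'   categories x features matrices.
#' @slot sharedFraction numeric in [0, 1].
#' @slot responseProfile data.frame with columns \code{time_ms} and
#'   \code{amplitude}; amplitude is zero before stimulus onset.
#' @slot noiseSd numeric, standard deviation of additive noise in signal
#'   units.
#' @slot seed integer used to draw the patterns.
#' @export
setClass("GroundTruth",
  representation(
    patterns = "list",
    sharedFraction = "numeric",
    responseProfile = "data.frame",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@sharedFraction) != 1 ||
      is.na(object@sharedFraction) ||
      object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must be a single value in [0, 1]")
  if (!all(vapply(object@patterns, function(p) all(is.finite(p)), logical(1))))
    msg <- c(msg, "all pattern matrices must be finite")
  rp <- object@responseProfile
  if (!all(c("time_ms", "amplitude") %in% names(rp)))
    msg <- c(msg, "responseProfile needs columns time_ms and amplitude")
  else if (any(rp$amplitude[rp$time_ms < 0] != 0))
    msg <- c(msg, "responseProfile must be zero before time 0")
  if (length(msg)) msg else TRUE
})

#' EpochSet: trial-segmented sensor data
#'
#' The MEG-side unit of analysis: a trials x channels x time array with a
#' category label and a depiction label per trial, on a uniform time grid
#' in milliseconds relative to stimulus onset.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot category integer category label per trial.
#' @slot depiction character depiction label per trial
#'   (photo/drawing/sketch).
#' @slot times numeric, ms relative to stimulus onset, strictly increasing
#'   and uniformly spaced at \code{1000/srate}.
#' @slot srate sampling rate in Hz.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    category = "integer",
    depiction = "character",
    times = "numeric",
    srate = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msg <- c(msg, "data must be a 3-D array (trials x channels x time)")
  else {
    if (d[1] != length(object@category))
      msg <- c(msg, "category length must equal the number of trials")
    if (d[1] != length(object@depiction))
      msg <- c(msg, "depiction length must equal the number of trials")
    if (d[3] != length(object@times))
      msg <- c(msg, "times length must equal the third data dimension")
  }
  if (anyNA(object@data))
    msg <- c(msg, "data must not contain NAs")
  tt <- object@times
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    step <- 1000 / object@srate
    if (max(abs(dt - step)) > 1e-6)
      msg <- c(msg, "times must be uniformly spaced at 1000/srate ms")
  }
  cells <- table(object@category, object@depiction)
  if (length(cells) && any(cells > 0 & cells < 2))
    msg <- c(msg, "each (category, depiction) cell needs at least 2 trials")
  if (length(msg)) msg else TRUE
})

#' BetaSet: run-wise fMRI response patterns
#'
#' The fMRI-side unit of analysis: a runs x conditions x voxels array of
#' GLM beta estimates, either for an ROI (arbitrary voxel set) or a
#' volumetric grid (0-based integer voxel coordinates, used by the
#' searchlight).
#'
#' @slot betas numeric array, runs x conditions x voxels.
#' @slot voxelCoords integer matrix, voxels x 3, 0-based grid coordinates.
#' @slot roiLabel character label for the voxel set.
#' @slot dims integer(3) grid dimensions (NA for pure ROI mode).
#' @slot signalVoxels integer indices of ground-truth signal voxels
#'   (empty when unknown).
#' @export
setClass("BetaSet",
  representation(
    betas = "array",
    voxelCoords = "matrix",
    roiLabel = "character",
    dims = "integer",
    signalVoxels = "integer"
  ),
  prototype(dims = rep(NA_integer_, 3), signalVoxels = integer())
)

setValidity("BetaSet", function(object) {
  msg <- character()
  d <- dim(object@betas)
  if (length(d) != 3)
    msg <- c(msg, "betas must be runs x conditions x voxels")
  else {
    if (d[1] < 2) msg <- c(msg, "at least 2 runs are required")
    if (nrow(object@voxelCoords) != d[3])
      msg <- c(msg, "voxelCoords rows must match the number of voxels")
  }
  if (anyDuplicated(object@voxelCoords))
    msg <- c(msg, "voxelCoords must be unique")
  if (length(msg)) msg else TRUE
})

#' GazeEpoch: a single trial of gaze position samples
#'
#' @slot x,y numeric gaze position in degrees of visual angle per sample.
#' @slot srate sampling rate in Hz.
#' @slot plantedSaccades data.frame of ground-truth saccades
#'   (\code{onset_sample}, \code{amplitude_deg}); empty for real data.
#' @export
setClass("GazeEpoch",
  representation(
    x = "numeric",
    y = "numeric",
    srate = "numeric",
    plantedSaccades = "data.frame"
  ),
  prototype(plantedSaccades = data.frame(onset_sample = integer(),
                                         amplitude_deg = numeric()))
)

setValidity("GazeEpoch", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have the same length")
  if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
    msg <- c(msg, "gaze samples must be finite")
  if (length(object@srate) != 1 || object@srate <= 0)
    msg <- c(msg, "srate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' SupertrialSet: trial averages used to boost SNR before classification
#'
#' Each supertrial is the mean of exactly \code{groupSize} distinct trials
#' of one category; within one assignment repetition, trials are
#' partitioned without reuse.
#'
#' @slot data numeric array, supertrials x channels x time.
#' @slot category integer category per supertrial.
#' @slot times numeric ms grid.
#' @slot groupSize integer, trials averaged per supertrial.
#' @slot assignmentRepetition integer index of the random assignment.
#' @export
setClass("SupertrialSet",
  representation(
    data = "array",
    category = "integer",
    times = "numeric",
    groupSize = "integer",
    assignmentRepetition = "integer"
  )
)

setValidity("SupertrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msg <- c(msg, "data must be supertrials x channels x time")
  else if (d[1] != length(object@category))
    msg <- c(msg, "category length must match number of supertrials")
  if (length(msg)) msg else TRUE
})

#' RDM: representational dissimilarity matrix
#'
#' Symmetric conditions x conditions matrix of pattern dissimilarities
#' (1 - Pearson correlation, hence in [0, 2]) with a zero diagonal.
#'
#' @slot values numeric matrix of dissimilarities.
#' @slot conditionIds character condition labels.
#' @export
setClass("RDM",
  representation(values = "matrix", conditionIds = "character")
)

setValidity("RDM", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (anyNA(v)) msg <- c(msg, "values must not contain NAs")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (max(abs(diag(v))) > 1e-8) msg <- c(msg, "diagonal must be zero")
    if (min(v) < -1e-8 || max(v) > 2 + 1e-8)
      msg <- c(msg, "entries must lie in [0, 2]")
  }
  if (length(object@conditionIds) != nrow(v))
    msg <- c(msg, "conditionIds must match matrix size")
  if (length(msg)) msg else TRUE
})

#' TimeCourse: one value per time point
#'
#' @slot values numeric; accuracies in percent or correlations.
#' @slot times numeric ms grid.
#' @slot chance numeric chance level in the same units (NA for
#'   correlations).
#' @slot metric character, "accuracy" or "correlation".
#' @export
setClass("TimeCourse",
  representation(values = "numeric", times = "numeric",
                 chance = "numeric", metric = "character"),
  prototype(chance = NA_real_, metric = "accuracy")
)

setValidity("TimeCourse", function(object) {
  msg <- character()
  if (length(object@values) != length(object@times))
    msg <- c(msg, "values and times must have equal length")
  if (object@metric == "accuracy" &&
      any(object@values < 0 | object@values > 100, na.rm = TRUE))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' TGMatrix: temporal generalization matrix
#'
#' Train-time x test-time decoding accuracies (percent); the diagonal
#' equals the time-resolved decoding computed with the same folds.
#'
#' @slot values numeric matrix, train x test.
#' @slot times numeric ms grid (shared by both axes).
#' @export
setClass("TGMatrix",
  representation(values = "matrix", times = "numeric")
)

setValidity("TGMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@times) ||
      ncol(object@values) != length(object@times))
    msg <- c(msg, "values must be times x times")
  if (any(object@values < 0 | object@values > 100, na.rm = TRUE))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' AccuracyMap: voxel-wise decoding accuracies on a grid
#'
#' @slot values numeric 3-D array of accuracies (percent), NA outside the
#'   mask.
#' @slot mask logical 3-D array.
#' @export
setClass("AccuracyMap",
  representation(values = "array", mask = "array")
)

setValidity("AccuracyMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  v <- object@values[object@mask]
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "values outside the mask must be NA")
  if (any(v < 0 | v > 100, na.rm = TRUE))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' FusionTimeCourse: MEG-fMRI fusion correlations over time
#'
#' @slot values numeric Pearson correlations in [-1, 1].
#' @slot times numeric ms grid.
#' @slot roi character ROI label.
#' @export
setClass("FusionTimeCourse",
  representation(values = "numeric", times = "numeric", roi = "character")
)

setValidity("FusionTimeCourse", function(object) {
  msg <- character()
  if (length(object@values) != length(object@times))
    msg <- c(msg, "values and times must have equal length")
  if (any(abs(object@values) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' PermTestResult: sign-permutation test output
#'
#' @slot pValues numeric p-value per sample point, bounded below by
#'   1/nPermutations (the observed permutation is always included).
#' @slot observed numeric observed group-mean statistic per point.
#' @slot nPermutations integer.
#' @slot tail character, "one" or "two".
#' @export
setClass("PermTestResult",
  representation(pValues = "numeric", observed = "numeric",
                 nPermutations = "integer", tail = "character")
)

setValidity("PermTestResult", function(object) {
  msg <- character()
  lo <- 1 / object@nPermutations
  if (any(object@pValues < lo - 1e-12 | object@pValues > 1 + 1e-12))
    msg <- c(msg, "p-values must lie in [1/nPermutations, 1]")
  if (!object@tail %in% c("one", "two"))
    msg <- c(msg, "tail must be 'one' or 'two'")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: cluster-size permutation correction output
#'
#' @slot clusters list of integer index vectors (disjoint, every member
#'   above the forming threshold).
#' @slot clusterP numeric p-value per cluster.
#' @slot formingThreshold numeric per-point statistic threshold used to
#'   form clusters.
#' @slot nullMaxSizes numeric permutation distribution of the maximum
#'   cluster size.
#' @slot alpha numeric cluster-level threshold.
#' @slot significant logical per cluster.
#' @export
setClass("ClusterResult",
  representation(clusters = "list", clusterP = "numeric",
                 formingThreshold = "numeric", nullMaxSizes = "numeric",
                 alpha = "numeric", significant = "logical")
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  all_idx <- unlist(object@clusters)
  if (anyDuplicated(all_idx)) msg <- c(msg, "clusters must be disjoint")
  if (length(object@clusterP) != length(object@clusters))
    msg <- c(msg, "one p-value per cluster required")
  if (length(msg)) msg else TRUE
})

#' PeakCI: bootstrap confidence interval for a peak latency
#'
#' @slot peakLatency numeric ms, argmax of the observed group mean (first
#'   index on ties).
#' @slot ciLow,ciHigh numeric ms bounds (mean +/- 1.96 SD of the bootstrap
#'   peak distribution).
#' @slot nBoot integer bootstrap samples.
#' @slot samples numeric bootstrap peak latencies (kept for downstream
#'   equivalence testing).
#' @export
setClass("PeakCI",
  representation(peakLatency = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", nBoot = "integer",
                 samples = "numeric")
)

#' HRFLibrary: candidate hemodynamic response functions
#'
#' A family of double-gamma kernels spanning peak times of roughly 4-8 s
#' and varying undershoot depth, each normalized to unit peak and sampled
#' on the TR grid.
#'
#' @slot kernels numeric matrix, samples x n kernels.
#' @slot trS numeric sampling interval in seconds.
#' @slot times numeric sample times in seconds.
#' @export
setClass("HRFLibrary",
  representation(kernels = "matrix", trS = "numeric", times = "numeric")
)

setValidity("HRFLibrary", function(object) {
  msg <- character()
  pk <- apply(object@kernels, 2, max)
  if (max(abs(pk - 1)) > 1e-6)
    msg <- c(msg, "each kernel must be normalized to unit peak")
  if (nrow(object@kernels) != length(object@times))
    msg <- c(msg, "times must match kernel length")
  if (length(msg)) msg else TRUE
})

#' GLMFit: HRF-selected first-level GLM results
#'
#' @slot betas numeric matrix, conditions x voxels, taken per voxel from
#'   the HRF with the minimum mean residual.
#' @slot chosenHrfIndex integer per voxel.
#' @slot meanResidual numeric matrix, voxels x HRFs.
#' @slot conditionIds character.
#' @export
setClass("GLMFit",
  representation(betas = "matrix", chosenHrfIndex = "integer",
                 meanResidual = "matrix", conditionIds = "character")
)

setValidity("GLMFit", function(object) {
  msg <- character()
  chosen <- apply(object@meanResidual, 1, which.min)
  if (!identical(as.integer(chosen), object@chosenHrfIndex))
    msg <- c(msg, "chosenHrfIndex must be the argmin of meanResidual")
  if (length(msg)) msg else TRUE
})
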