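#' Detect microsaccades by the velocity-threshold method
#'
#' Velocities are computed with a 5-sample moving-window differentiator;
#' a per-axis threshold is set at \code{lambdaThreshold} times a
#' median-based velocity SD, and samples exceeding the elliptic
#' criterion \code{(vx/ex)^2 + (vy/ey)^2 > 1} for at least
#' \code{minDurationSamples} consecutive samples form a saccade.
#' Amplitude is the displacement between onset and offset positions.
#' Monocular traces are assumed.
#'
#' @param gaze a \linkS4class{GazeEpoch}.
#' @param lambdaThreshold velocity threshold multiplier (default 6).
#' @param minDurationSamples minimum run length (default 3).
#' @return data.frame with one row per saccade: \code{onset_sample},
#'   \code{offset_sample}, \code{amplitude_deg},
#'   \code{peak_velocity_deg_s}.
#' @export
detectMicrosaccades <- function(gaze, lambdaThreshold = 6,
                                minDurationSamples = 3) {
  assertNumber(lambdaThreshold, "lambdaThreshold", min = 0)
  assertCount(minDurationSamples, "minDurationSamples")
  x <- gaze@x; y <- gaze@y; sr <- gaze@srate
  n <- length(x)
  if (n < minDurationSamples + 4)
    stopf("epoch too short: need at least %d samples",
          minDurationSamples + 4)
  vx <- movingWindowVelocity(x, sr)
  vy <- movingWindowVelocity(y, sr)
  # median-based SD estimator, robust to the saccades themselves
  msdx <- sqrt(stats::median(vx^2) - stats::median(vx)^2)
  msdy <- sqrt(stats::median(vy^2) - stats::median(vy)^2)
  if (msdx < 1e-10) msdx <- 1e-10
  if (msdy < 1e-10) msdy <- 1e-10
  ex <- lambdaThreshold * msdx
  ey <- lambdaThreshold * msdy
  supra <- (vx / ex)^2 + (vy / ey)^2 > 1
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= minDurationSamples
  if (!any(keep))
    return(data.frame(onset_sample = integer(),
                      offset_sample = integer(),
                      amplitude_deg = numeric(),
                      peak_velocity_deg_s = numeric()))
  on <- starts[keep]; off <- ends[keep]
  data.frame(
    onset_sample = on, offset_sample = off,
    amplitude_deg = sqrt((x[off] - x[on])^2 + (y[off] - y[on])^2),
    peak_velocity_deg_s = vapply(seq_along(on), function(k)
      max(sqrt(vx[on[k]:off[k]]^2 + vy[on[k]:off[k]]^2)), numeric(1))
  )
}

# 5-sample moving-window differentiator: v[n] =
# (p[n+2] + p[n+1] - p[n-1] - p[n-2]) * srate / 6, edges zero-padded.
movingWindowVelocity <- function(p, srate) {
  n <- length(p)
  v <- numeric(n)
  idx <- 3:(n - 2)
  v[idx] <- (p[idx + 2] + p[idx + 1] - p[idx - 1] - p[idx - 2]) *
    srate / 6
  v
}

#' Remove slow drift from a gaze epoch
#'
#' First-order detrending (removal of the least-squares linear trend per
#' axis), the package's implementation of slow-drift high-pass
#' filtering before saccade detection.
#'
#' @param gaze a \linkS4class{GazeEpoch}.
#' @return a detrended \linkS4class{GazeEpoch}.
#' @export
detrendGaze <- function(gaze) {
  t <- seq_along(gaze@x)
  initialize(gaze,
             x = stats::residuals(stats::lm.fit(cbind(1, t),
                                                gaze@x)) + mean(gaze@x),
             y = stats::residuals(stats::lm.fit(cbind(1, t),
                                                gaze@y)) + mean(gaze@y))
}

#' Label trials by on-stimulus eye movements
#'
#' Runs the detector on each epoch; epochs containing any movement with
#' amplitude above \code{dropDeg} (default 3 degrees — too large to have
#' landed on the stimulus) are dropped from consideration, and the
#' remaining trials are flagged as containing an eye movement on the
#' stimulus when any saccade amplitude exceeds \code{flagDeg} (default
#' 1.5 degrees).
#'
#' @param epochs list of \linkS4class{GazeEpoch}.
#' @param dropDeg amplitude above which an epoch is dropped.
#' @param flagDeg amplitude above which a retained trial is flagged.
#' @param lambdaThreshold,minDurationSamples detector parameters.
#' @param detrend apply \code{\link{detrendGaze}} first.
#' @return data.frame with one row per epoch: \code{dropped},
#'   \code{on_stimulus} (NA for dropped epochs), \code{max_amplitude}.
#' @export
filterAndLabel <- function(epochs, dropDeg = 3, flagDeg = 1.5,
                           lambdaThreshold = 6,
                           minDurationSamples = 3, detrend = FALSE) {
  res <- lapply(epochs, function(g) {
    if (detrend) g <- detrendGaze(g)
    s <- detectMicrosaccades(g, lambdaThreshold, minDurationSamples)
    maxamp <- if (nrow(s)) max(s$amplitude_deg) else 0
    dropped <- maxamp > dropDeg
    data.frame(dropped = dropped,
               on_stimulus = if (dropped) NA else maxamp > flagDeg,
               max_amplitude = maxamp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out[, c("trial", "dropped", "on_stimulus", "max_amplitude")]
}

#' Contamination ratio and subject-exclusion rule
#'
#' Ratio of trials flagged as containing on-stimulus eye movements to
#' all experimental (non-catch) trials; subjects exceeding 5%
#' (strictly) are excluded.
#'
#' @param flags logical on-stimulus flags (NAs — dropped epochs — are
#'   ignored in the numerator).
#' @param nExperimentalTrials total experimental trial count.
#' @param threshold exclusion threshold (default 0.05).
#' @return list with \code{ratio} and \code{exclude}.
#' @export
contaminationRatio <- function(flags, nExperimentalTrials,
                               threshold = 0.05) {
  assertCount(nExperimentalTrials, "nExperimentalTrials")
  ratio <- sum(flags, na.rm = TRUE) / nExperimentalTrials
  list(ratio = ratio, exclude = ratio > threshold)
}
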