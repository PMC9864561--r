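# Peak latency of a group-mean curve: first index of the maximum inside
# the window (ties resolved to the earliest sample).
peakOfMean <- function(mat, times, window) {
  inwin <- times >= window[1] & times <= window[2]
  mu <- colMeans(mat)[inwin]
  times[inwin][which.max(mu)]
}

#' Bootstrap confidence interval for a peak latency
#'
#' Resamples subjects with replacement, recomputes the group-mean time
#' course and its peak latency per bootstrap sample, and reports the 95%
#' CI as mean +/- 1.96 SD of the bootstrap peak-latency distribution.
#' The peak is the argmax of the group mean within \code{window}; on
#' ties the first (earliest) maximum is taken. Restricting the window is
#' useful when a curve's global maximum lies outside the epoch of
#' interest.
#'
#' @param timecourses subjects x time matrix.
#' @param times numeric ms grid.
#' @param nBoot bootstrap samples (study default 100,000).
#' @param window numeric(2) ms window for peak detection (default: the
#'   whole grid).
#' @param seed integer RNG seed.
#' @return a \linkS4class{PeakCI}; the bootstrap peak samples are kept
#'   in the \code{samples} slot for equivalence testing.
#' @export
bootstrapPeak <- function(timecourses, times, nBoot = 100000,
                          window = range(times), seed = 1) {
  timecourses <- as.matrix(timecourses)
  if (nrow(timecourses) < 2) stopf("at least 2 subjects are required")
  if (ncol(timecourses) != length(times))
    stopf("times must match the number of columns")
  if (window[1] < min(times) || window[2] > max(times))
    stopf("window must lie within the time grid")
  assertCount(nBoot, "nBoot", min = 1)
  mu <- colMeans(timecourses)
  inwin <- times >= window[1] & times <= window[2]
  if (max(mu[inwin]) - min(mu[inwin]) < .Machine$double.eps * 100)
    warning("flat curve inside the window: peak latency is tie-broken ",
            "to the earliest sample", call. = FALSE)
  n <- nrow(timecourses)
  peaks <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      peakOfMean(timecourses[idx, , drop = FALSE], times, window)
    }, numeric(1))
  })
  new("PeakCI", peakLatency = peakOfMean(timecourses, times, window),
      ciLow = mean(peaks) - 1.96 * stats::sd(peaks),
      ciHigh = mean(peaks) + 1.96 * stats::sd(peaks),
      nBoot = as.integer(nBoot), samples = peaks)
}

#' Bootstrap CI for the difference of two peak latencies
#'
#' Paired bootstrap: the same subject resample is applied to both
#' conditions, the two peak latencies are computed per sample, and their
#' difference collected; the 95% CI is mean +/- 1.96 SD of the
#' difference distribution. The difference is flagged significant when
#' the CI excludes zero.
#'
#' @param tcA,tcB subjects x time matrices on the same grid (same
#'   subjects, paired).
#' @param times numeric ms grid.
#' @param nBoot bootstrap samples.
#' @param window numeric(2) ms peak-detection window.
#' @param seed integer RNG seed.
#' @return list with \code{difference} (observed peak A - peak B),
#'   \code{ciLow}, \code{ciHigh}, \code{significant}, and the bootstrap
#'   difference \code{samples}.
#' @export
bootstrapPeakDifference <- function(tcA, tcB, times, nBoot = 10000,
                                    window = range(times), seed = 1) {
  tcA <- as.matrix(tcA); tcB <- as.matrix(tcB)
  if (!identical(dim(tcA), dim(tcB)))
    stopf("the two time-course matrices must have identical shape")
  if (ncol(tcA) != length(times))
    stopf("times must match the number of columns")
  n <- nrow(tcA)
  diffs <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      peakOfMean(tcA[idx, , drop = FALSE], times, window) -
        peakOfMean(tcB[idx, , drop = FALSE], times, window)
    }, numeric(1))
  })
  lo <- mean(diffs) - 1.96 * stats::sd(diffs)
  hi <- mean(diffs) + 1.96 * stats::sd(diffs)
  list(difference = peakOfMean(tcA, times, window) -
         peakOfMean(tcB, times, window),
       ciLow = lo, ciHigh = hi,
       significant = lo > 0 || hi < 0,
       samples = diffs)
}

#' TOST equivalence test for peak latencies
#'
#' Two one-sided tests against the equivalence bounds
#' \code{+/- boundsMs}: p is the larger of the p-values for
#' (mean difference > -bound) and (mean difference < +bound). Small p
#' supports equivalence within the bounds. For bootstrap samples the SD
#' of the difference distribution already estimates the standard error
#' of the mean-difference estimator, so a z statistic is used; for
#' subject-level samples a paired one-sample t test is used. Bounds are
#' a scientific choice and must be supplied by the caller.
#'
#' @param samplesA,samplesB numeric vectors of equal length: paired
#'   bootstrap peak-latency samples (\code{type = "bootstrap"}) or
#'   subject-level latencies (\code{type = "subjects"}).
#' @param boundsMs positive equivalence bound in ms.
#' @param type variance estimator, see Details.
#' @return list with \code{p} (the TOST p-value), the two one-sided
#'   p-values, and the mean difference.
#' @export
tostEquivalence <- function(samplesA, samplesB, boundsMs,
                            type = c("bootstrap", "subjects")) {
  type <- match.arg(type)
  if (missing(boundsMs) || is.null(boundsMs))
    stopf("equivalence bounds (boundsMs) are required and are never defaulted")
  assertNumber(boundsMs, "boundsMs", min = 0)
  if (boundsMs <= 0) stopf("boundsMs must be > 0")
  if (length(samplesA) != length(samplesB))
    stopf("samples must be paired (equal length)")
  d <- samplesA - samplesB
  md <- mean(d)
  if (type == "bootstrap") {
    se <- stats::sd(d)
    if (se == 0) se <- .Machine$double.eps
    p_lower <- stats::pnorm((md - (-boundsMs)) / se,
                            lower.tail = FALSE)
    p_upper <- stats::pnorm((boundsMs - md) / se, lower.tail = FALSE)
  } else {
    se <- stats::sd(d) / sqrt(length(d))
    if (se == 0) se <- .Machine$double.eps
    df <- length(d) - 1
    p_lower <- stats::pt((md + boundsMs) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((boundsMs - md) / se, df, lower.tail = FALSE)
  }
  list(p = max(p_lower, p_upper), p_lower = p_lower, p_upper = p_upper,
       meanDifference = md)
}
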