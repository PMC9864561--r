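#' Library of candidate hemodynamic response functions
#'
#' A parameterized family of 20 double-gamma kernels spanning
#' time-to-peak values of roughly 4-8 s with covarying undershoot depth,
#' each normalized to unit peak and sampled on the TR grid. A custom
#' kernel matrix (samples x kernels, e.g. loaded from an external HRF
#' library file) can be supplied instead via \code{kernels}.
#'
#' @param trS repetition time in seconds.
#' @param lengthS kernel support in seconds.
#' @param n number of kernels.
#' @param kernels optional precomputed samples x kernels matrix
#'   (peak-normalized on return).
#' @return an \linkS4class{HRFLibrary}.
#' @export
hrfLibrary <- function(trS = 1.5, lengthS = 30, n = 20,
                       kernels = NULL) {
  tt <- seq(0, lengthS, by = trS)
  if (is.null(kernels)) {
    peaks <- seq(4, 8, length.out = n)
    undershoot <- seq(0.25, 0.45, length.out = n)
    kernels <- vapply(seq_len(n), function(i) {
      p <- peaks[i]
      # gamma with mode p (shape a, rate b: mode = (a-1)/b)
      b <- 1.0
      a <- p * b + 1
      h <- stats::dgamma(tt, shape = a, rate = b) -
        undershoot[i] * stats::dgamma(tt, shape = a + 8, rate = b)
      h / max(h)
    }, numeric(length(tt)))
  } else {
    kernels <- apply(as.matrix(kernels), 2, function(h) h / max(h))
    tt <- seq(0, by = trS, length.out = nrow(kernels))
  }
  new("HRFLibrary", kernels = kernels, trS = trS, times = tt)
}

#' Build a first-level design matrix
#'
#' One column per condition: the boxcar of that condition's event
#' onsets/durations is convolved with the HRF on a fine time grid and
#' sampled at the TR. Events are validated against the scan duration.
#'
#' @param events data.frame with columns \code{onset}, \code{duration}
#'   (seconds) and \code{condition}.
#' @param hrf numeric kernel sampled at \code{trS} (one column of an
#'   \linkS4class{HRFLibrary}).
#' @param nScans number of volumes.
#' @param trS repetition time in seconds.
#' @param dt fine-grid resolution in seconds for the convolution.
#' @return numeric matrix, scans x conditions, with condition names as
#'   column names.
#' @export
buildDesign <- function(events, hrf, nScans, trS, dt = 0.1) {
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(events)))
    stopf("events needs columns %s", paste(need, collapse = ", "))
  dur_total <- nScans * trS
  if (any(events$onset < 0) ||
      any(events$onset + events$duration > dur_total))
    stopf("events must lie within the scan duration (0..%g s)",
          dur_total)
  if (any(events$duration <= 0))
    stopf("event durations must be positive")
  ev <- events[order(events$onset), ]
  if (nrow(ev) > 1 &&
      any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)] - 1e-9))
    stopf("overlapping events are not valid in this design")
  conds <- sort(unique(as.character(events$condition)))
  fine_t <- seq(0, dur_total, by = dt)
  hrf_fine <- stats::approx(seq(0, by = trS,
                                length.out = length(hrf)),
                            hrf, xout = seq(0, (length(hrf) - 1) * trS,
                                            by = dt),
                            rule = 2)$y
  scan_t <- (seq_len(nScans) - 1) * trS
  x <- vapply(conds, function(cc) {
    e <- events[as.character(events$condition) == cc, , drop = FALSE]
    box <- numeric(length(fine_t))
    for (k in seq_len(nrow(e))) {
      on <- e$onset[k]; off <- e$onset[k] + e$duration[k]
      box[fine_t >= on & fine_t < off] <- 1
    }
    conv <- stats::convolve(box, rev(hrf_fine), type = "open")
    conv <- conv[seq_along(fine_t)] * dt
    stats::approx(fine_t, conv, xout = scan_t, rule = 2)$y
  }, numeric(nScans))
  colnames(x) <- conds
  x
}

#' Fit an HRF-selected first-level GLM
#'
#' Fits the GLM once per candidate HRF (ordinary least squares, with
#' intercept and optional nuisance regressors) and, per voxel, keeps the
#' betas from the HRF that yielded the minimum mean residual for that
#' voxel. This approximates the voxel's true HRF without biasing
#' group-level statistics.
#'
#' @param bold scans x voxels numeric matrix.
#' @param events data.frame (\code{onset}, \code{duration},
#'   \code{condition}).
#' @param hrfs an \linkS4class{HRFLibrary}.
#' @param nuisance optional scans x k nuisance regressor matrix (see
#'   \code{\link{nuisanceRegressors}}).
#' @param trS repetition time in seconds.
#' @return a \linkS4class{GLMFit}.
#' @export
fitHrfSelectedGlm <- function(bold, events, hrfs = hrfLibrary(trS),
                              nuisance = NULL, trS = 1.5) {
  bold <- as.matrix(bold)
  if (!all(is.finite(bold))) stopf("bold must be finite")
  n_scans <- nrow(bold); n_vox <- ncol(bold)
  n_h <- ncol(hrfs@kernels)
  n_cond <- length(unique(as.character(events$condition)))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (ncol(nuisance) >= n_scans - n_cond)
      stopf("too many nuisance columns (%d) for %d scans and %d conditions",
            ncol(nuisance), n_scans, n_cond)
  }
  mean_resid <- matrix(NA_real_, n_vox, n_h)
  betas_by_h <- vector("list", n_h)
  for (h in seq_len(n_h)) {
    task <- buildDesign(events, hrfs@kernels[, h], n_scans, trS)
    x <- cbind(task, intercept = 1, nuisance)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
      stopf("rank-deficient design: collinear column(s) %s",
            paste(dropped, collapse = ", "))
    }
    fit <- qr.coef(qx, bold)
    res <- bold - x %*% fit
    mean_resid[, h] <- colMeans(res^2)
    betas_by_h[[h]] <- fit[seq_len(ncol(task)), , drop = FALSE]
  }
  chosen <- apply(mean_resid, 1, which.min)
  conds <- rownames(betas_by_h[[1]])
  betas <- vapply(seq_len(n_vox), function(v)
    betas_by_h[[chosen[v]]][, v], numeric(length(conds)))
  betas <- matrix(betas, nrow = length(conds),
                  dimnames = list(conds, NULL))
  new("GLMFit", betas = betas, chosenHrfIndex = as.integer(chosen),
      meanResidual = mean_resid, conditionIds = conds)
}

#' Screen and interpolate outlier volumes
#'
#' Flags volumes whose framewise intensity difference, scaled relative
#' to the mean difference across the series, exceeds
#' \code{intensityFold} (default 30-fold), or whose frame-to-frame
#' displacement exceeds \code{maxDisplacementMm} (default 0.5 mm) on any
#' motion axis. Flagged volumes are replaced by linear interpolation of
#' the nearest clean neighbors (nearest-neighbor extension at the series
#' edges, which is reported).
#'
#' @param bold scans x voxels matrix.
#' @param motionParams optional scans x k motion parameter matrix
#'   (mm / radians).
#' @param intensityFold scaled intensity-difference threshold.
#' @param maxDisplacementMm per-axis displacement threshold.
#' @return list with \code{outliers} (volume indices),
#'   \code{interpolated} (the cleaned scans x voxels matrix), and
#'   \code{scaledDiff}.
#' @export
detectOutlierVolumes <- function(bold, motionParams = NULL,
                                 intensityFold = 30,
                                 maxDisplacementMm = 0.5) {
  bold <- as.matrix(bold)
  n <- nrow(bold)
  if (n < 3) stopf("at least 3 volumes are required")
  d <- rowMeans(abs(bold[-1, , drop = FALSE] -
                    bold[-n, , drop = FALSE]))
  scaled <- d / mean(d)
  flagged <- rep(FALSE, n)
  flagged[which(scaled > intensityFold) + 1L] <- TRUE
  if (!is.null(motionParams)) {
    mp <- as.matrix(motionParams)
    disp <- abs(mp[-1, , drop = FALSE] - mp[-n, , drop = FALSE])
    flagged[which(apply(disp, 1, max) > maxDisplacementMm) + 1L] <- TRUE
  }
  out <- which(flagged)
  clean <- bold
  if (length(out)) {
    good <- which(!flagged)
    if (!length(good)) stopf("all volumes flagged as outliers")
    edge <- out[out < min(good) | out > max(good)]
    if (length(edge))
      message("outlier volume(s) at the series edge extended from the ",
              "nearest clean neighbor: ", paste(edge, collapse = ", "))
    for (v in seq_len(ncol(bold)))
      clean[out, v] <- stats::approx(good, bold[good, v], xout = out,
                                     rule = 2)$y
  }
  list(outliers = out, interpolated = clean, scaledDiff = scaled)
}

#' Extract noise components from noise-voxel time series
#'
#' Principal components of the standardized time series of anatomically
#' defined noise voxels (white matter / CSF), returned as orthonormal
#' scan-wise regressors — the component-based noise correction used as
#' nuisance regressors in the first-level GLM.
#'
#' @param noiseSeries scans x voxels matrix of noise-voxel time series.
#' @param nComponents number of components to keep.
#' @return scans x nComponents matrix with orthonormal columns.
#' @export
extractNoiseComponents <- function(noiseSeries, nComponents) {
  x <- as.matrix(noiseSeries)
  assertCount(nComponents, "nComponents")
  if (ncol(x) < nComponents)
    stopf("need at least nComponents (%d) noise voxels, got %d",
          nComponents, ncol(x))
  x <- scale(x)
  x[is.na(x)] <- 0
  sv <- svd(x, nu = min(nrow(x), ncol(x)), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (nComponents > rank)
    stopf("nComponents (%d) exceeds the rank (%d) of the noise series",
          nComponents, rank)
  sv$u[, seq_len(nComponents), drop = FALSE]
}

#' Assemble the standard nuisance regressor set
#'
#' Noise components plus motion parameters and their first- and
#' second-order derivatives (backward differences, zero-padded).
#'
#' @param noiseComponents scans x k matrix (or NULL).
#' @param motionParams scans x m matrix (or NULL).
#' @return scans x p nuisance matrix.
#' @export
nuisanceRegressors <- function(noiseComponents = NULL,
                               motionParams = NULL) {
  pieces <- list()
  if (!is.null(noiseComponents))
    pieces$noise <- as.matrix(noiseComponents)
  if (!is.null(motionParams)) {
    mp <- as.matrix(motionParams)
    d1 <- rbind(0, diff(mp))
    d2 <- rbind(0, diff(d1))
    pieces$motion <- cbind(mp, d1, d2)
  }
  if (!length(pieces)) stopf("no nuisance inputs supplied")
  do.call(cbind, pieces)
}
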