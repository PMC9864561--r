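#' Constructors for the core data containers
#'
#' Thin validated constructors; most users obtain these objects from the
#' simulators or the readers instead.
#'
#' @param data numeric array, trials x channels x time.
#' @param category integer category label per trial.
#' @param depiction character depiction label per trial.
#' @param times numeric ms grid.
#' @param srate sampling rate in Hz.
#' @return an \linkS4class{EpochSet}.
#' @export
EpochSet <- function(data, category, depiction, times,
                     srate = 1000 / diff(times[1:2])) {
  new("EpochSet", data = data, category = as.integer(category),
      depiction = as.character(depiction), times = as.numeric(times),
      srate = srate)
}

#' @rdname EpochSet
#' @param betas numeric array, runs x conditions x voxels.
#' @param voxelCoords integer matrix voxels x 3 (0-based).
#' @param roiLabel character.
#' @param dims integer(3) grid dimensions or NA.
#' @param signalVoxels integer indices of true signal voxels.
#' @export
BetaSet <- function(betas, voxelCoords = NULL, roiLabel = "roi",
                    dims = rep(NA_integer_, 3),
                    signalVoxels = integer()) {
  if (is.null(voxelCoords))
    voxelCoords <- cbind(seq_len(dim(betas)[3]) - 1L, 0L, 0L)
  storage.mode(voxelCoords) <- "integer"
  new("BetaSet", betas = betas, voxelCoords = voxelCoords,
      roiLabel = roiLabel, dims = as.integer(dims),
      signalVoxels = as.integer(signalVoxels))
}

#' @rdname EpochSet
#' @param x,y gaze position in degrees of visual angle.
#' @param plantedSaccades data.frame of ground-truth saccades.
#' @export
GazeEpoch <- function(x, y, srate,
                      plantedSaccades = data.frame(
                        onset_sample = integer(),
                        amplitude_deg = numeric())) {
  new("GazeEpoch", x = as.numeric(x), y = as.numeric(y), srate = srate,
      plantedSaccades = plantedSaccades)
}

#' Default epoch time grid
#'
#' -100..1000 ms in 10 ms steps (100 Hz), i.e. the 111-sample grid that
#' results from segmenting -100..1001 ms at 1000 Hz and downsampling by 10.
#'
#' @return numeric vector of 111 times in ms.
#' @export
defaultEpochTimes <- function() {
  downsampleTimes(seq(-100, 1001, by = 1), 10L)
}

#' Default evoked response profile
#'
#' A transient Gaussian bump peaking at \code{peak_ms} (default 100 ms)
#' with SD \code{width_ms}, zero before stimulus onset. Amplitude is in
#' signal units and multiplies the category pattern at each time point.
#'
#' @param times numeric ms grid.
#' @param peak_ms peak latency of the evoked response.
#' @param width_ms Gaussian SD in ms.
#' @param amplitude peak amplitude.
#' @return data.frame with columns \code{time_ms}, \code{amplitude}.
#' @export
defaultResponseProfile <- function(times = defaultEpochTimes(),
                                   peak_ms = 100, width_ms = 40,
                                   amplitude = 1) {
  a <- amplitude * exp(-0.5 * ((times - peak_ms) / width_ms)^2)
  a[times < 0] <- 0
  data.frame(time_ms = times, amplitude = a)
}

#' Generate ground-truth category patterns
#'
#' Draws one latent pattern per category and depiction as
#' \code{sqrt(sharedFraction) * common + sqrt(1 - sharedFraction) *
#' specific}, with the common and depiction-specific components iid
#' standard normal. The expected correlation between the patterns of the
#' same category in two depictions is \code{sharedFraction}, which makes
#' the generator's cross-decoding behaviour controllable: 1 means an
#' identical representational format across depictions, 0 means unrelated
#' formats.
#'
#' @param nCategories number of object categories (study design: 48).
#' @param nFeatures latent feature dimensionality.
#' @param sharedFraction fraction of pattern variance shared across
#'   depictions, in [0, 1].
#' @param noiseSd default noise SD stored for the simulators.
#' @param responseProfile data.frame (\code{time_ms}, \code{amplitude});
#'   defaults to \code{\link{defaultResponseProfile}}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeGroundTruth(8, 20, sharedFraction = 0.5, seed = 1)
#' @export
makeGroundTruth <- function(nCategories = 48, nFeatures = 100,
                            sharedFraction = 0.5, noiseSd = 1,
                            responseProfile = NULL, seed = 1) {
  assertCount(nCategories, "nCategories", min = 3)
  assertCount(nFeatures, "nFeatures", min = 2)
  assertNumber(sharedFraction, "sharedFraction", 0, 1)
  assertNumber(noiseSd, "noiseSd", min = 0)
  if (is.null(responseProfile))
    responseProfile <- defaultResponseProfile()
  patterns <- withSeed(seed, {
    common <- matrix(rnorm(nCategories * nFeatures), nCategories)
    lapply(stats::setNames(DEPICTION_LEVELS, DEPICTION_LEVELS),
           function(d) {
      specific <- matrix(rnorm(nCategories * nFeatures), nCategories)
      sqrt(sharedFraction) * common + sqrt(1 - sharedFraction) * specific
    })
  })
  new("GroundTruth", patterns = patterns,
      sharedFraction = sharedFraction,
      responseProfile = responseProfile, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# Orthonormal random map (nrow x ncol, nrow >= ncol: orthonormal columns;
# otherwise orthonormal rows), so injected signal energy is comparable
# across seeds.
orthonormalMap <- function(nrow, ncol) {
  if (nrow >= ncol) qr.Q(qr(matrix(rnorm(nrow * ncol), nrow)))
  else t(qr.Q(qr(matrix(rnorm(nrow * ncol), ncol))))
}

#' Simulate MEG-like epochs from ground truth
#'
#' Each trial is \code{profile(t) * (mixing \%*\% pattern)} plus Gaussian
#' noise, where the mixing is a fixed orthonormal channels x features map
#' per seed. Noise is iid per channel and time point by default; supplying
#' \code{channelCov} (an SPD matrix, or \code{"random"}) draws spatially
#' correlated noise to exercise multivariate noise normalization.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param nTrialsPerCell trials per (category, depiction) cell; must be
#'   even so supertrials of two divide evenly (study design: 24).
#' @param nChannels number of sensors (study design: 306).
#' @param times ms grid (default the 111-point grid).
#' @param depictions subset of depiction types to simulate.
#' @param noiseSd noise SD; defaults to the value stored in \code{gt}.
#' @param channelCov NULL, an SPD channels x channels matrix, or
#'   \code{"random"}.
#' @param seed integer RNG seed.
#' @return an \linkS4class{EpochSet}.
#' @export
simulateEpochs <- function(gt, nTrialsPerCell = 24, nChannels = 306,
                           times = defaultEpochTimes(),
                           depictions = names(gt@patterns),
                           noiseSd = gt@noiseSd, channelCov = NULL,
                           seed = 1) {
  assertCount(nTrialsPerCell, "nTrialsPerCell", min = 2)
  if (nTrialsPerCell %% 2 != 0)
    stopf("nTrialsPerCell must be even (got %d): supertrials of two must divide the trial count evenly",
          nTrialsPerCell)
  depictions <- match.arg(depictions, names(gt@patterns),
                          several.ok = TRUE)
  nFeat <- ncol(gt@patterns[[1]])
  nCat <- nrow(gt@patterns[[1]])
  profile <- stats::approx(gt@responseProfile$time_ms,
                           gt@responseProfile$amplitude, xout = times,
                           rule = 2)$y
  profile[times < 0] <- 0

  withSeed(seed, {
    mixing <- orthonormalMap(nChannels, nFeat)
    chol_cov <- NULL
    if (!is.null(channelCov)) {
      if (identical(channelCov, "random")) {
        a <- matrix(rnorm(nChannels * nChannels), nChannels)
        channelCov <- crossprod(a) / nChannels + diag(nChannels) * 0.1
      }
      chol_cov <- chol(channelCov)
    }
    nTrials <- nTrialsPerCell * nCat * length(depictions)
    category <- rep(rep(seq_len(nCat), each = nTrialsPerCell),
                    times = length(depictions))
    depiction <- rep(depictions, each = nTrialsPerCell * nCat)
    data <- array(0, c(nTrials, nChannels, length(times)))
    for (i in seq_len(nTrials)) {
      sig <- outer(drop(mixing %*% gt@patterns[[depiction[i]]][category[i], ]),
                   profile)
      noise <- matrix(rnorm(nChannels * length(times), sd = noiseSd),
                      nChannels)
      if (!is.null(chol_cov)) noise <- crossprod(chol_cov, noise)
      data[i, , ] <- sig + noise
    }
    EpochSet(data, category, depiction, times,
             srate = 1000 / diff(times[1:2]))
  })
}

#' Ground-truth patterns for one depiction
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param depiction depiction label.
#' @return categories x features matrix.
#' @export
truePatterns <- function(gt, depiction = "photo") {
  gt@patterns[[match.arg(depiction, names(gt@patterns))]]
}

#' Simulate epochs with two representational stages
#'
#' Emulates a signal whose representational geometry changes over time:
#' an "early" pattern set active under \code{profileEarly} (e.g. peaking
#' at 100 ms, the geometry of an early visual region) and a "late"
#' pattern set active under \code{profileLate} (e.g. peaking at 150 ms,
#' a higher-level region), sharing one sensor mixing. Fusion of the
#' resulting epochs with the two geometries' RDMs should recover the
#' injected latency ordering.
#'
#' @param gtEarly,gtLate \linkS4class{GroundTruth} objects with equal
#'   category/feature counts; their \code{responseProfile}s define the
#'   two stages' time courses.
#' @param nTrialsPerCell trials per category (single depiction
#'   "photo" is simulated).
#' @param nChannels number of sensors.
#' @param times ms grid.
#' @param noiseSd additive noise SD.
#' @param seed integer RNG seed.
#' @return an \linkS4class{EpochSet}.
#' @export
simulateTwoStageEpochs <- function(gtEarly, gtLate, nTrialsPerCell = 8,
                                   nChannels = 32,
                                   times = defaultEpochTimes(),
                                   noiseSd = 1, seed = 1) {
  pe <- truePatterns(gtEarly); pl <- truePatterns(gtLate)
  if (!identical(dim(pe), dim(pl)))
    stopf("the two ground truths must have matching pattern shapes")
  prof <- function(gt) {
    p <- stats::approx(gt@responseProfile$time_ms,
                       gt@responseProfile$amplitude, xout = times,
                       rule = 2)$y
    p[times < 0] <- 0
    p
  }
  prof_e <- prof(gtEarly); prof_l <- prof(gtLate)
  nCat <- nrow(pe)
  withSeed(seed, {
    mix_e <- orthonormalMap(nChannels, ncol(pe))
    mix_l <- orthonormalMap(nChannels, ncol(pl))
    n <- nTrialsPerCell * nCat
    category <- rep(seq_len(nCat), each = nTrialsPerCell)
    data <- array(0, c(n, nChannels, length(times)))
    for (i in seq_len(n)) {
      sig <- outer(drop(mix_e %*% pe[category[i], ]), prof_e) +
        outer(drop(mix_l %*% pl[category[i], ]), prof_l)
      data[i, , ] <- sig +
        matrix(rnorm(nChannels * length(times), sd = noiseSd),
               nChannels)
    }
    EpochSet(data, category, rep("photo", n), times,
             srate = 1000 / diff(times[1:2]))
  })
}

#' Simulate run-wise fMRI beta patterns
#'
#' ROI mode (\code{grid = NULL}): every voxel carries signal through an
#' orthonormal features x voxels map, plus run-specific Gaussian noise.
#' Grid mode: voxels tile a 3-D grid; signal is confined to a compact
#' spherical blob inside the grid (all other voxels are pure noise), which
#' gives searchlight recovery tests a known target.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param nRuns number of runs (study design: 4).
#' @param nVoxels voxels in ROI mode.
#' @param noiseSd run-specific noise SD.
#' @param depiction which depiction's patterns to use.
#' @param grid integer(3) grid dimensions, or NULL for ROI mode.
#' @param blobCenter integer(3) 0-based blob center (default: grid
#'   center).
#' @param blobRadius blob radius in voxels.
#' @param signalScale multiplier on the injected patterns.
#' @param seed integer RNG seed.
#' @return a \linkS4class{BetaSet}; in grid mode \code{dims} and
#'   \code{signalVoxels} record the geometry.
#' @export
simulateBetas <- function(gt, nRuns = 4, nVoxels = 60, noiseSd = 1,
                          depiction = "photo", grid = NULL,
                          blobCenter = NULL, blobRadius = 2,
                          signalScale = 1, seed = 1) {
  assertCount(nRuns, "nRuns", min = 2)
  assertNumber(noiseSd, "noiseSd", min = 0)
  pat <- gt@patterns[[match.arg(depiction, names(gt@patterns))]]
  nCat <- nrow(pat)

  withSeed(seed, {
    if (is.null(grid)) {
      w <- orthonormalMap(ncol(pat), nVoxels)
      mu <- signalScale * pat %*% w
      coords <- cbind(seq_len(nVoxels) - 1L, 0L, 0L)
      dims <- rep(NA_integer_, 3)
      signal <- seq_len(nVoxels)
    } else {
      grid <- as.integer(grid)
      if (length(grid) != 3 || any(grid < 1))
        stopf("grid must be three positive integers")
      if (is.null(blobCenter)) blobCenter <- (grid - 1L) %/% 2L
      if (any(blobCenter - blobRadius < 0) ||
          any(blobCenter + blobRadius > grid - 1L))
        stopf("grid smaller than blob: radius %g around (%s) leaves the %s grid",
              blobRadius, paste(blobCenter, collapse = ","),
              paste(grid, collapse = "x"))
      coords <- as.matrix(expand.grid(x = 0:(grid[1] - 1),
                                      y = 0:(grid[2] - 1),
                                      z = 0:(grid[3] - 1)))
      d2 <- colSums((t(coords) - blobCenter)^2)
      signal <- which(d2 <= blobRadius^2)
      nVoxels <- nrow(coords)
      w <- orthonormalMap(ncol(pat), length(signal))
      mu <- matrix(0, nCat, nVoxels)
      mu[, signal] <- signalScale * pat %*% w
      dims <- grid
    }
    betas <- array(0, c(nRuns, nCat, nVoxels))
    for (r in seq_len(nRuns))
      betas[r, , ] <- mu + matrix(rnorm(nCat * nVoxels, sd = noiseSd),
                                  nCat)
    BetaSet(betas, voxelCoords = coords, roiLabel = depiction,
            dims = dims, signalVoxels = signal)
  })
}

#' Simulate BOLD time series from known betas and HRFs
#'
#' Generates \code{Y = X(hrf) \%*\% B + noise} per voxel, where X is the
#' boxcar design convolved with the library HRF of the voxel's
#' \code{hrfIndex}. Used to test the HRF-selected GLM by parameter
#' recovery.
#'
#' @param events data.frame with columns \code{onset}, \code{duration}
#'   (seconds) and \code{condition}.
#' @param hrfIndex integer HRF library index, scalar or one per voxel.
#' @param trueBetas conditions x voxels matrix of true amplitudes.
#' @param noiseSd Gaussian noise SD.
#' @param nScans number of volumes.
#' @param trS repetition time in seconds (study design: 1.5 s).
#' @param hrfs an \linkS4class{HRFLibrary}; default
#'   \code{hrfLibrary(trS)}.
#' @param seed integer RNG seed.
#' @return numeric matrix, scans x voxels, with the design-bearing events
#'   attached as attribute \code{"events"}.
#' @export
simulateBold <- function(events, hrfIndex, trueBetas, noiseSd = 0,
                         nScans = 200, trS = 1.5, hrfs = NULL,
                         seed = 1) {
  if (is.null(hrfs)) hrfs <- hrfLibrary(trS)
  nH <- ncol(hrfs@kernels)
  if (any(hrfIndex < 1 | hrfIndex > nH))
    stopf("hrfIndex must lie in 1..%d", nH)
  trueBetas <- as.matrix(trueBetas)
  nVox <- ncol(trueBetas)
  hrfIndex <- rep_len(as.integer(hrfIndex), nVox)
  designs <- lapply(sort(unique(hrfIndex)), function(h)
    buildDesign(events, hrfs@kernels[, h], nScans, trS))
  names(designs) <- sort(unique(hrfIndex))
  withSeed(seed, {
    y <- vapply(seq_len(nVox), function(v) {
      x <- designs[[as.character(hrfIndex[v])]]
      drop(x %*% trueBetas[, v]) + rnorm(nScans, sd = noiseSd)
    }, numeric(nScans))
    structure(y, events = events, trS = trS,
              true_hrf_index = hrfIndex)
  })
}

# Minimum-jerk displacement profile on [0, 1].
minimumJerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate gaze traces with planted saccades
#'
#' Fixation is Gaussian positional noise; planted saccades follow a
#' smooth minimum-jerk displacement profile with a main-sequence-like
#' duration (21 ms + 2.2 ms/deg), so their peak velocity comfortably
#' exceeds the velocity-threshold criterion of the detector at realistic
#' noise levels.
#'
#' @param nTrials number of gaze epochs.
#' @param nSamples samples per epoch.
#' @param srate sampling rate in Hz (study hardware: 1000 Hz).
#' @param fixationNoiseSd positional noise SD in degrees.
#' @param saccadeSpecs NULL, a data.frame with columns
#'   \code{onset_sample}, \code{amplitude_deg} (applied to every trial),
#'   or a list of such data.frames, one per trial.
#' @param seed integer RNG seed.
#' @return list of \linkS4class{GazeEpoch}, ground truth recorded in
#'   \code{plantedSaccades}.
#' @export
simulateGaze <- function(nTrials = 1, nSamples = 600, srate = 1000,
                         fixationNoiseSd = 0.01, saccadeSpecs = NULL,
                         seed = 1) {
  assertCount(nTrials, "nTrials")
  if (is.data.frame(saccadeSpecs))
    saccadeSpecs <- rep(list(saccadeSpecs), nTrials)
  if (!is.null(saccadeSpecs) && length(saccadeSpecs) != nTrials)
    stopf("saccadeSpecs must have one element per trial")
  withSeed(seed, {
    lapply(seq_len(nTrials), function(tr) {
      x <- rnorm(nSamples, sd = fixationNoiseSd)
      y <- rnorm(nSamples, sd = fixationNoiseSd)
      spec <- if (is.null(saccadeSpecs)) NULL else saccadeSpecs[[tr]]
      if (!is.null(spec) && nrow(spec)) {
        if (any(spec$amplitude_deg < 0))
          stopf("saccade amplitudes must be >= 0")
        for (k in seq_len(nrow(spec))) {
          amp <- spec$amplitude_deg[k]
          on <- spec$onset_sample[k]
          dur <- max(8L, round((21 + 2.2 * amp) * srate / 1000))
          idx <- on:min(nSamples, on + dur - 1L)
          tau <- seq(0, 1, length.out = dur)[seq_along(idx)]
          theta <- runif(1, 0, 2 * pi)
          disp <- amp * minimumJerk(tau)
          x[idx] <- x[idx] + cos(theta) * disp
          y[idx] <- y[idx] + sin(theta) * disp
          if (max(idx) < nSamples) {
            rest <- (max(idx) + 1):nSamples
            x[rest] <- x[rest] + cos(theta) * amp
            y[rest] <- y[rest] + sin(theta) * amp
          }
        }
      }
      GazeEpoch(x, y, srate,
                plantedSaccades = if (is.null(spec))
                  data.frame(onset_sample = integer(),
                             amplitude_deg = numeric())
                else spec[, c("onset_sample", "amplitude_deg")])
    })
  })
}

#' Simulate a run-wise trial sequence with catch trials
#'
#' Builds the presentation order of one experiment: per run, each image
#' appears \code{perRun} times in randomized order without immediate
#' repeats, interleaved with catch trials. Catch placement follows either
#' the spacing rule (one catch after every \code{catchSpacing} image
#' presentations) or a target proportion; the two parameterizations are
#' deliberately independent. Per-trial durations are stimulus duration
#' plus an ISI drawn uniformly from the given grid.
#'
#' @param nRuns runs in the session.
#' @param perRun presentations of each image per run.
#' @param nImages number of images (study design: 48).
#' @param stimMs stimulus duration in ms.
#' @param isiMs vector of candidate ISIs in ms for experimental trials.
#' @param catchIsiMs vector of candidate ISIs for catch trials.
#' @param catchSpacing integer vector: a catch follows after this many
#'   image presentations (sampled per catch); used when
#'   \code{catchMode = "spacing"}.
#' @param catchProportion target fraction of catch trials; used when
#'   \code{catchMode = "proportion"}.
#' @param catchMode placement rule.
#' @param seed integer RNG seed.
#' @return data.frame (run, position, type, image, duration_ms) with the
#'   timing parameters stored as attributes; summarize with
#'   \code{\link{sequenceSummary}}.
#' @export
simulateTrialSequence <- function(nRuns = 3, perRun = 8, nImages = 48,
                                  stimMs = 450,
                                  isiMs = seq(250, 450, 50),
                                  catchIsiMs = seq(1050, 1250, 50),
                                  catchSpacing = 4:6,
                                  catchProportion = 0.2,
                                  catchMode = c("spacing", "proportion"),
                                  seed = 1) {
  catchMode <- match.arg(catchMode)
  assertCount(nRuns, "nRuns")
  assertCount(perRun, "perRun")
  assertNumber(catchProportion, "catchProportion", 0, 0.5)
  withSeed(seed, {
    runs <- lapply(seq_len(nRuns), function(r) {
      imgs <- sampleNoRepeat(rep(seq_len(nImages), perRun))
      n <- length(imgs)
      gaps <- if (catchMode == "spacing") {
        g <- integer(0); pos <- 0
        repeat {
          pos <- pos + sample(catchSpacing, 1)
          if (pos > n) break
          g <- c(g, pos)
        }
        g
      } else {
        nc <- round(catchProportion / (1 - catchProportion) * n)
        sort(sample(n, min(nc, n)))
      }
      type <- character(0); image <- integer(0)
      j <- 1
      for (i in seq_len(n)) {
        type <- c(type, "experimental"); image <- c(image, imgs[i])
        while (j <= length(gaps) && gaps[j] == i) {
          type <- c(type, "catch"); image <- c(image, NA_integer_)
          j <- j + 1
        }
      }
      dur <- ifelse(type == "catch",
                    stimMs + sample(catchIsiMs, length(type), TRUE),
                    stimMs + sample(isiMs, length(type), TRUE))
      data.frame(run = r, position = seq_along(type), type = type,
                 image = image, duration_ms = dur)
    })
    structure(do.call(rbind, runs), stim_ms = stimMs, isi_ms = isiMs,
              catch_isi_ms = catchIsiMs)
  })
}

# Random permutation with no two equal adjacent entries: shuffle, then
# repair adjacent duplicates by swapping with a randomly chosen
# position where the swap creates no new conflict.
sampleNoRepeat <- function(x) {
  s <- sample(x)
  n <- length(s)
  for (pass in 1:100) {
    bad <- which(s[-1] == s[-n]) + 1L
    if (!length(bad)) return(s)
    for (i in bad) {
      if (s[i] != s[i - 1]) next  # fixed by an earlier swap
      for (j in sample(n)) {
        ok_j <- s[i] != (if (j > 1) s[j - 1] else NA) &&
          s[i] != (if (j < n) s[j + 1] else NA) && abs(j - i) > 1
        ok_i <- s[j] != s[i - 1] &&
          (i == n || s[j] != s[i + 1])
        if (isTRUE(ok_j) && isTRUE(ok_i)) {
          tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
          break
        }
      }
    }
  }
  s
}

#' Summarize a simulated trial sequence
#'
#' Reports presentations per image across runs and the expected trial
#' durations implied by the sequence's stimulus duration and ISI grids
#' (stimulus + mean ISI), together with the empirical mean durations of
#' the generated sequence.
#'
#' @param seq output of \code{\link{simulateTrialSequence}}.
#' @return list with counts and durations (ms).
#' @export
sequenceSummary <- function(seq) {
  counts <- table(seq$image[seq$type == "experimental"])
  exp_ms <- attr(seq, "stim_ms") + mean(attr(seq, "isi_ms"))
  catch_ms <- attr(seq, "stim_ms") + mean(attr(seq, "catch_isi_ms"))
  list(
    presentations_per_image = as.integer(counts),
    n_runs = length(unique(seq$run)),
    n_catch = sum(seq$type == "catch"),
    catch_fraction = mean(seq$type == "catch"),
    expected_experimental_ms = exp_ms,
    expected_catch_ms = catch_ms,
    empirical_experimental_ms =
      mean(seq$duration_ms[seq$type == "experimental"]),
    empirical_catch_ms = mean(seq$duration_ms[seq$type == "catch"])
  )
}
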