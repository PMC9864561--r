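#' Multivariate noise normalization of epochs
#'
#' Whitens channels by the inverse square root of a shrinkage-regularized
#' channel covariance estimated from epoch residuals (per-cell,
#' per-time-point means removed). Shrinkage follows the Ledoit-Wolf
#' estimator toward a scaled identity, which keeps the covariance
#' invertible for few trials and many channels.
#'
#' @param epochs an \linkS4class{EpochSet} with at least 2 trials per
#'   condition cell.
#' @param shrinkage "lw" (Ledoit-Wolf, default) or "none".
#' @return an \linkS4class{EpochSet} of identical shape with whitened
#'   channels.
#' @export
noiseNormalize <- function(epochs, shrinkage = c("lw", "none")) {
  shrinkage <- match.arg(shrinkage)
  d <- epochs@data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_t <- dim(d)[3]
  cell <- interaction(epochs@category, epochs@depiction, drop = TRUE)
  resid <- d
  for (g in levels(cell)) {
    idx <- which(cell == g)
    mu <- apply(d[idx, , , drop = FALSE], c(2, 3), mean)
    for (i in idx) resid[i, , ] <- d[i, , ] - mu
  }
  # Pool residuals over trials and time points: rows are observations.
  x <- matrix(aperm(resid, c(2, 1, 3)), nrow = n_ch)  # ch x (tr*t)
  x <- t(x)
  n <- nrow(x)
  s <- crossprod(x) / n
  if (shrinkage == "lw") {
    m <- mean(diag(s))
    d2 <- sum((s - diag(m, n_ch))^2) / n_ch
    b2bar <- 0
    # second moment of sample covariance around s, computed in chunks
    step <- max(1L, floor(1e6 / n_ch^2))
    for (start in seq(1, n, by = step)) {
      rows <- start:min(n, start + step - 1L)
      for (i in rows) {
        xi <- x[i, ]
        b2bar <- b2bar + sum((tcrossprod(xi) - s)^2)
      }
    }
    b2 <- min(b2bar / (n^2 * n_ch), d2)
    rho <- if (d2 > 0) b2 / d2 else 1
    sigma <- rho * diag(m, n_ch) + (1 - rho) * s
  } else {
    sigma <- s
  }
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 1e-10 * max(e$values))
    stopf(paste("channel covariance is numerically singular;",
                "use shrinkage = 'lw' or supply more trials"))
  w <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  out <- d
  for (i in seq_len(n_tr)) out[i, , ] <- w %*% d[i, , ]
  initialize(epochs, data = out)
}

#' Subset an EpochSet by depiction and/or category
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param depiction optional depiction label(s) to keep.
#' @param categories optional category labels to keep.
#' @return an \linkS4class{EpochSet}.
#' @export
subsetEpochs <- function(epochs, depiction = NULL, categories = NULL) {
  keep <- rep(TRUE, dim(epochs@data)[1])
  if (!is.null(depiction)) keep <- keep & epochs@depiction %in% depiction
  if (!is.null(categories)) keep <- keep & epochs@category %in% categories
  if (!any(keep)) stopf("no trials left after subsetting")
  initialize(epochs, data = epochs@data[keep, , , drop = FALSE],
             category = epochs@category[keep],
             depiction = epochs@depiction[keep])
}

#' Randomly permute category labels across trials
#'
#' Utility for chance-level calibration: destroys the label-pattern
#' association while keeping the data and label counts intact.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param seed integer RNG seed.
#' @return an \linkS4class{EpochSet} with shuffled category labels.
#' @export
permuteCategoryLabels <- function(epochs, seed = 1) {
  withSeed(seed,
    initialize(epochs, category = sample(epochs@category)))
}

#' Average trials into supertrials
#'
#' Randomly partitions the trials of each category into disjoint groups
#' of \code{groupSize} and averages each group into one supertrial
#' (24 trials with groups of 2 yield 12 supertrials per category). The
#' whole assignment is repeated \code{nRepetitions} times with fresh
#' random partitions; downstream decoding averages over repetitions.
#'
#' @param epochs an \linkS4class{EpochSet} holding a single depiction
#'   type.
#' @param groupSize trials averaged per supertrial (default 2).
#' @param nRepetitions number of random assignments (default 5).
#' @param seed integer RNG seed.
#' @return list of \linkS4class{SupertrialSet}, one per repetition.
#' @export
makeSupertrials <- function(epochs, groupSize = 2L, nRepetitions = 5L,
                            seed = 1) {
  assertCount(groupSize, "groupSize")
  assertCount(nRepetitions, "nRepetitions")
  if (length(unique(epochs@depiction)) > 1)
    stopf("epochs hold multiple depictions; subsetEpochs() first")
  counts <- table(epochs@category)
  if (any(counts %% groupSize != 0))
    stopf("trials per category (%s) must be divisible by groupSize = %d",
          paste(unique(counts), collapse = ", "), groupSize)
  cats <- sort(unique(epochs@category))
  n_ch <- dim(epochs@data)[2]; n_t <- dim(epochs@data)[3]
  withSeed(seed, {
    lapply(seq_len(nRepetitions), function(rep_i) {
      st_data <- list(); st_cat <- integer(0)
      for (cc in cats) {
        idx <- sample(which(epochs@category == cc))
        groups <- split(idx, ceiling(seq_along(idx) / groupSize))
        for (g in groups) {
          avg <- apply(epochs@data[g, , , drop = FALSE], c(2, 3), mean)
          st_data[[length(st_data) + 1L]] <- avg
          st_cat <- c(st_cat, cc)
        }
      }
      arr <- array(0, c(length(st_data), n_ch, n_t))
      for (i in seq_along(st_data)) arr[i, , ] <- st_data[[i]]
      new("SupertrialSet", data = arr, category = st_cat,
          times = epochs@times, groupSize = as.integer(groupSize),
          assignmentRepetition = as.integer(rep_i))
    })
  })
}

# Train a linear SVM on (x, y) and return predictions for newx.
# Non-convergence (never observed with libsvm in practice, but guarded)
# yields NULL: the caller skips the fold and logs it.
svmPredict <- function(x, y, newx, cost = 1) {
  fit <- tryCatch(
    e1071::svm(x = x, y = factor(y), kernel = "linear", cost = cost,
               scale = FALSE, type = "C-classification"),
    error = function(e) {
      warning("classifier failed on one fold; fold skipped (",
              conditionMessage(e), ")", call. = FALSE)
      NULL
    })
  if (is.null(fit)) return(NULL)
  as.character(predict(fit, newx))
}

# Pairwise leave-one-supertrial-out accuracy for one pattern matrix
# (rows = supertrials) and one test matrix per fold index; the engine
# shared by within- and cross-decoding. trainX/testX: items x features;
# trainY/testY: labels. Folds leave out one item per class by index.
pairwiseLOOAccuracy <- function(trainX, trainY, testX, testY,
                                cost = 1) {
  cats <- sort(unique(trainY))
  pairs <- utils::combn(cats, 2)
  acc <- numeric(ncol(pairs)); used <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ia_tr <- which(trainY == a); ib_tr <- which(trainY == b)
    ia_te <- which(testY == a); ib_te <- which(testY == b)
    nf <- min(length(ia_tr), length(ib_tr))
    correct <- 0; total <- 0
    for (k in seq_len(nf)) {
      tr_idx <- c(ia_tr[-k], ib_tr[-k])
      te_idx <- c(ia_te[k], ib_te[k])
      pred <- svmPredict(trainX[tr_idx, , drop = FALSE],
                         trainY[tr_idx],
                         testX[te_idx, , drop = FALSE], cost)
      if (is.null(pred)) next
      correct <- correct + sum(pred == as.character(testY[te_idx]))
      total <- total + length(te_idx)
    }
    if (total > 0) { acc[p] <- correct / total; used[p] <- TRUE }
  }
  if (!any(used)) return(NA_real_)
  mean(acc[used]) * 100
}

#' Time-resolved pairwise decoding of category from supertrials
#'
#' For every time point and every unordered pair of categories, a linear
#' SVM (C = 1) is evaluated with leave-one-supertrial-out
#' cross-validation (one supertrial per class left out per fold);
#' accuracies are averaged over pairs, folds, and assignment repetitions.
#' Chance is 50%.
#'
#' @param supertrialSets list of \linkS4class{SupertrialSet} (from
#'   \code{\link{makeSupertrials}}).
#' @param cost SVM regularization parameter.
#' @return a \linkS4class{TimeCourse} (accuracy in percent).
#' @export
pairwiseDecodeTimecourse <- function(supertrialSets, cost = 1) {
  checkSupertrialSets(supertrialSets)
  times <- supertrialSets[[1]]@times
  n_t <- length(times)
  acc <- matrix(NA_real_, length(supertrialSets), n_t)
  for (r in seq_along(supertrialSets)) {
    st <- supertrialSets[[r]]
    for (t in seq_len(n_t)) {
      x <- st@data[, , t, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, ncol = 1)
      acc[r, t] <- pairwiseLOOAccuracy(x, st@category, x, st@category,
                                       cost)
    }
  }
  new("TimeCourse", values = colMeans(acc, na.rm = TRUE), times = times,
      chance = 50, metric = "accuracy")
}

checkSupertrialSets <- function(sets) {
  if (!length(sets)) stopf("at least one SupertrialSet is required")
  counts <- table(sets[[1]]@category)
  if (length(counts) < 2) stopf("at least 2 categories are required")
  if (any(counts < 3))
    stopf("at least 3 supertrials per category are required")
  invisible(TRUE)
}

#' ROI-wise pairwise decoding of fMRI beta patterns
#'
#' Leave-one-run-out cross-validation: for every unordered pair of
#' conditions, classifiers train on the pattern vectors of all runs but
#' one and test on the held-out run, until each run served as test;
#' accuracies are averaged over pairs and folds.
#'
#' @param betas a \linkS4class{BetaSet}.
#' @param cost SVM regularization parameter.
#' @return accuracy in percent (chance 50).
#' @export
pairwiseDecodeROI <- function(betas, cost = 1) {
  b <- betas@betas
  decodeRunsPairwise(b, b, cost)
}

# Leave-one-run-out pairwise accuracy, training on runs of `train` and
# testing on the held-out run of `test` (train/test may be the same
# array, or two depictions for cross-decoding).
decodeRunsPairwise <- function(train, test, cost = 1) {
  n_runs <- dim(train)[1]; n_cond <- dim(train)[2]
  if (dim(test)[1] != n_runs || dim(test)[2] != n_cond)
    stopf("train and test beta arrays must share runs and conditions")
  if (n_runs < 2) stopf("at least 2 runs are required")
  pairs <- utils::combn(n_cond, 2)
  acc <- numeric(ncol(pairs)); used <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    correct <- 0; total <- 0
    nv <- dim(train)[3]
    for (r in seq_len(n_runs)) {
      tr <- rbind(matrix(train[-r, a, ], ncol = nv),
                  matrix(train[-r, b, ], ncol = nv))
      y <- rep(c("a", "b"), each = n_runs - 1)
      te <- rbind(matrix(test[r, a, ], ncol = nv),
                  matrix(test[r, b, ], ncol = nv))
      pred <- svmPredict(tr, y, te, cost)
      if (is.null(pred)) next
      correct <- correct + sum(pred == c("a", "b"))
      total <- total + 2
    }
    if (total > 0) { acc[p] <- correct / total; used[p] <- TRUE }
  }
  if (!any(used)) return(NA_real_)
  mean(acc[used]) * 100
}

#' Searchlight decoding over a voxel grid
#'
#' For every in-mask voxel, the pattern vector holds the betas of all
#' in-mask voxels within Euclidean distance \code{radiusVoxels} (voxel
#' units, center included); the sphere's accuracy comes from the same
#' leave-one-run-out pairwise scheme as \code{\link{pairwiseDecodeROI}}
#' and is assigned to the center. The finished map is optionally smoothed
#' with a Gaussian kernel (FWHM in mm, truncated at 4 SD). Centers whose
#' sphere holds fewer than 2 voxels are skipped and reported.
#'
#' @param betas a \linkS4class{BetaSet} in grid mode.
#' @param mask logical 3-D array; default: all voxels present in
#'   \code{betas}.
#' @param radiusVoxels sphere radius in voxels (default 4).
#' @param smoothingFwhmMm smoothing kernel FWHM in mm (0 = none).
#' @param voxelSizeMm isotropic voxel size in mm (acquisition: 2.5 mm).
#' @param cost SVM regularization parameter.
#' @param crossBetas optional second \linkS4class{BetaSet} on the same
#'   grid: train/test across the two sets (direction-averaged)
#'   instead of within.
#' @return an \linkS4class{AccuracyMap}.
#' @export
searchlightDecode <- function(betas, mask = NULL, radiusVoxels = 4,
                              smoothingFwhmMm = 5, voxelSizeMm = 2.5,
                              cost = 1, crossBetas = NULL) {
  assertNumber(radiusVoxels, "radiusVoxels", min = 1)
  if (anyNA(betas@dims))
    stopf("searchlight requires a grid-mode BetaSet (dims set)")
  dims <- betas@dims
  vox_lin <- betas@voxelCoords %*% c(1, dims[1], dims[1] * dims[2]) + 1
  index <- array(NA_integer_, dims)
  index[vox_lin] <- seq_len(nrow(betas@voxelCoords))
  if (is.null(mask)) mask <- !is.na(index)
  if (!identical(dim(mask), dim(index)))
    stopf("mask dimensions must match the beta grid")
  if (!any(mask)) stopf("mask is empty")
  inmask <- mask & !is.na(index)

  off <- sphereOffsets(radiusVoxels)

  vals <- array(NA_real_, dims)
  centers <- which(inmask, arr.ind = TRUE)
  skipped <- 0L
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    nb <- sweep(off, 2, ctr, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    vi <- index[nb]
    vi <- vi[!is.na(vi) & inmask[nb]]
    if (length(vi) < 2) { skipped <- skipped + 1L; next }
    sub <- betas@betas[, , vi, drop = FALSE]
    vals[ctr[1], ctr[2], ctr[3]] <-
      if (is.null(crossBetas)) decodeRunsPairwise(sub, sub, cost)
      else {
        sub2 <- crossBetas@betas[, , vi, drop = FALSE]
        mean(c(decodeRunsPairwise(sub, sub2, cost),
               decodeRunsPairwise(sub2, sub, cost)))
      }
  }
  if (skipped > 0)
    message(skipped, " searchlight center(s) skipped (sphere < 2 voxels)")
  outmask <- inmask & !is.na(vals)
  vals[!outmask] <- NA_real_
  if (smoothingFwhmMm > 0)
    vals <- gaussianSmoothMap(vals, outmask,
                              smoothingFwhmMm / voxelSizeMm)
  new("AccuracyMap", values = vals, mask = outmask)
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer (x, y, z) offsets with squared Euclidean norm at most
#' \code{radius^2} (center included); at the study's radius of 4 voxels
#' this is the 257-voxel sphere.
#'
#' @param radius sphere radius in voxel units.
#' @return integer matrix, offsets x 3.
#' @export
sphereOffsets <- function(radius) {
  assertNumber(radius, "radius", min = 1)
  r <- floor(radius)
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  off[rowSums(off^2) <= radius^2, , drop = FALSE]
}

# Gaussian smoothing of an in-mask 3-D map; fwhm_vox in voxel units,
# kernel truncated at 4 SD, weights renormalized inside the mask.
gaussianSmoothMap <- function(vals, mask, fwhm_vox) {
  sd_vox <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sd_vox))
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  wts <- exp(-rowSums(off^2) / (2 * sd_vox^2))
  keep <- rowSums(off^2) <= (4 * sd_vox)^2
  off <- off[keep, , drop = FALSE]; wts <- wts[keep]
  dims <- dim(vals)
  out <- vals
  centers <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    nb <- sweep(off, 2, ctr, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]; w <- wts[ok]
    v <- vals[nb]
    good <- !is.na(v)
    out[ctr[1], ctr[2], ctr[3]] <- sum(v[good] * w[good]) / sum(w[good])
  }
  out
}

#' Cross-decoding between two stimulus families
#'
#' Trains on data from one family (e.g. photographs) and tests on the
#' other (e.g. drawings), computes both train-test directions, and
#' averages them, with the fold structure mirroring the corresponding
#' within-family scheme. High cross-decoding indicates a shared
#' representational format.
#'
#' @param a,b for \code{mode = "timecourse"}: lists of
#'   \linkS4class{SupertrialSet} (paired by repetition); for
#'   \code{mode = "roi"}: \linkS4class{BetaSet}s over the same
#'   conditions; for \code{mode = "searchlight"}: grid-mode
#'   \linkS4class{BetaSet}s on the same grid.
#' @param mode decoding variant.
#' @param cost SVM regularization parameter.
#' @param ... passed to \code{\link{searchlightDecode}} in searchlight
#'   mode.
#' @return a \linkS4class{TimeCourse}, a single accuracy, or an
#'   \linkS4class{AccuracyMap}, matching the within-decoding shape.
#' @export
crossDecode <- function(a, b, mode = c("timecourse", "roi",
                                       "searchlight"),
                        cost = 1, ...) {
  mode <- match.arg(mode)
  if (mode == "roi") {
    if (!identical(dim(a@betas)[1:2], dim(b@betas)[1:2]))
      stopf("label mismatch: the two BetaSets must share runs and conditions")
    return(mean(c(decodeRunsPairwise(a@betas, b@betas, cost),
                  decodeRunsPairwise(b@betas, a@betas, cost))))
  }
  if (mode == "searchlight")
    return(searchlightDecode(a, cost = cost, crossBetas = b, ...))
  checkSupertrialSets(a); checkSupertrialSets(b)
  if (length(a) != length(b))
    stopf("the two supertrial lists must have equal repetitions")
  if (!identical(sort(unique(a[[1]]@category)),
                 sort(unique(b[[1]]@category))))
    stopf("label mismatch: the two sets must share categories")
  times <- a[[1]]@times
  n_t <- length(times)
  acc <- matrix(NA_real_, length(a), n_t)
  for (r in seq_along(a)) {
    sa <- a[[r]]; sb <- b[[r]]
    for (t in seq_len(n_t)) {
      xa <- matrix(sa@data[, , t], nrow = dim(sa@data)[1])
      xb <- matrix(sb@data[, , t], nrow = dim(sb@data)[1])
      ab <- pairwiseLOOAccuracy(xa, sa@category, xb, sb@category, cost)
      ba <- pairwiseLOOAccuracy(xb, sb@category, xa, sa@category, cost)
      acc[r, t] <- mean(c(ab, ba), na.rm = TRUE)
    }
  }
  new("TimeCourse", values = colMeans(acc, na.rm = TRUE), times = times,
      chance = 50, metric = "accuracy")
}

#' Temporal generalization of category decoding
#'
#' For every training time point, classifiers are trained exactly as in
#' \code{\link{pairwiseDecodeTimecourse}} (same folds) and tested at
#' every time point, yielding a train x test accuracy matrix whose
#' diagonal reproduces the time-resolved decoding.
#'
#' @param supertrialSets list of \linkS4class{SupertrialSet}.
#' @param cost SVM regularization parameter.
#' @return a \linkS4class{TGMatrix}.
#' @export
temporalGeneralization <- function(supertrialSets, cost = 1) {
  checkSupertrialSets(supertrialSets)
  times <- supertrialSets[[1]]@times
  n_t <- length(times)
  total <- array(0, c(n_t, n_t)); count <- array(0, c(n_t, n_t))
  for (r in seq_along(supertrialSets)) {
    st <- supertrialSets[[r]]
    cats <- sort(unique(st@category))
    pairs <- utils::combn(cats, 2)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      ia <- which(st@category == a); ib <- which(st@category == b)
      nf <- min(length(ia), length(ib))
      for (k in seq_len(nf)) {
        tr_idx <- c(ia[-k], ib[-k]); te_idx <- c(ia[k], ib[k])
        y <- st@category[tr_idx]
        for (t1 in seq_len(n_t)) {
          trx <- matrix(st@data[tr_idx, , t1],
                        nrow = length(tr_idx))
          # test patterns for both held-out supertrials at all times
          tex <- rbind(t(matrix(st@data[te_idx[1], , ],
                                nrow = dim(st@data)[2])),
                       t(matrix(st@data[te_idx[2], , ],
                                nrow = dim(st@data)[2])))
          pred <- svmPredict(trx, y, tex, cost)
          if (is.null(pred)) next
          truth <- rep(as.character(st@category[te_idx]), each = n_t)
          hit <- matrix(pred == truth, nrow = n_t)  # times x 2
          total[t1, ] <- total[t1, ] + rowSums(hit)
          count[t1, ] <- count[t1, ] + 2
        }
      }
    }
  }
  vals <- 100 * total / pmax(count, 1)
  vals[count == 0] <- NA_real_
  new("TGMatrix", values = vals, times = times)
}
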