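#' Sign-permutation test on subject-level effects
#'
#' Nonparametric group test: the sign of each subject's effect (already
#' centered on the null, e.g. accuracy - 50 or correlation - 0) is
#' flipped at random, the group mean recomputed, and the p-value per
#' point is the proportion of sign-flipped means at least as extreme as
#' the observed mean. The observed (identity) permutation is always
#' included, so the smallest attainable p is 1/nPerm. When all 2^n sign
#' patterns fit within \code{nPerm} the test enumerates them exhaustively
#' and is exact.
#'
#' @param effects subjects x points matrix (a vector is treated as one
#'   point per entry? no: a vector is a single-point effect per subject).
#' @param nPerm number of permutations (study default 10,000).
#' @param tail "one" (greater) or "two".
#' @param seed integer RNG seed (ignored when enumerating).
#' @param exhaustive force or forbid exhaustive enumeration; default:
#'   enumerate when 2^nsubjects <= nPerm.
#' @return a \linkS4class{PermTestResult}.
#' @export
signPermutationTest <- function(effects, nPerm = 10000,
                                tail = c("one", "two"), seed = 1,
                                exhaustive = NULL) {
  tail <- match.arg(tail)
  assertCount(nPerm, "nPerm", min = 1)
  effects <- as.matrix(effects)
  n <- nrow(effects)
  if (n < 2) stopf("at least 2 subjects are required")
  if (is.null(exhaustive)) exhaustive <- n <= 30 && 2^n <= nPerm
  obs <- colMeans(effects)
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- withSeed(seed,
      matrix(sample(c(-1, 1), (nPerm - 1) * n, replace = TRUE),
             nPerm - 1, n))
    signs <- rbind(rep(1, n), signs)  # observed permutation included
  }
  null_means <- (signs %*% effects) / n
  p <- if (tail == "one")
    colMeans(null_means >= rep(obs, each = nrow(signs)) - 1e-12)
  else
    colMeans(abs(null_means) >= rep(abs(obs), each = nrow(signs)) - 1e-12)
  new("PermTestResult", pValues = pmax(p, 1 / nrow(signs)),
      observed = obs, nPermutations = as.integer(nrow(signs)),
      tail = tail)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control; returns the rejection mask at
#' level \code{q}.
#'
#' @param pValues numeric vector in [0, 1].
#' @param q FDR level.
#' @return logical mask, TRUE where rejected.
#' @export
fdrBH <- function(pValues, q = 0.05) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH") <= q
}

# Connected components of a set of suprathreshold points.
# adjacency: "time" (consecutive indices), or a list(dims=, conn=) for
# grid data: conn 4 for time x time matrices, conn 26 for voxel grids.
# Points are linear indices into the grid (column-major), matching the
# columns of the effects matrix.
clusterComponents <- function(supra, adjacency) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  if (identical(adjacency, "time")) {
    breaks <- c(0, which(diff(idx) > 1), length(idx))
    return(lapply(seq_len(length(breaks) - 1), function(k)
      idx[(breaks[k] + 1):breaks[k + 1]]))
  }
  dims <- adjacency$dims
  conn <- adjacency$conn %||% if (length(dims) == 2) 4L else 26L
  nd <- length(dims)
  offsets <- switch(as.character(conn),
    "4" = matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), 4, 2),
    "26" = {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g[rowSums(abs(g)) > 0, , drop = FALSE]
    },
    "6" = matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0,
                   0, 0, -1, 0, 0, 1), 6, 3, byrow = TRUE),
    stopf("unsupported connectivity %s", conn))
  inset <- logical(prod(dims)); inset[idx] <- TRUE
  coords <- arrayInd(idx, dims)
  lookup <- stats::setNames(seq_along(idx), idx)
  visited <- logical(length(idx))
  comps <- list()
  for (s in seq_along(idx)) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; comp <- idx[s]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- coords[cur, ]
      nb <- sweep(offsets, 2, cc, "+")
      ok <- rep(TRUE, nrow(nb))
      for (d in seq_len(nd))
        ok <- ok & nb[, d] >= 1 & nb[, d] <= dims[d]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- as.vector(nb %*% cumprod(c(1, dims[-nd])) -
                       sum(cumprod(c(1, dims[-nd]))) + 1)
      lin <- lin[inset[lin]]
      for (l in lin) {
        j <- lookup[[as.character(l)]]
        if (!visited[j]) {
          visited[j] <- TRUE; queue <- c(queue, j); comp <- c(comp, l)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Cluster-size permutation correction
#'
#' Sign-permutation inference with multiple-comparison control via the
#' null distribution of the maximum cluster size: per permutation, the
#' group-mean statistic is recomputed, thresholded at the per-point
#' (1 - formingP) permutation quantile, clustered by adjacency, and the
#' maximum cluster size recorded. Observed clusters are significant when
#' their size exceeds the (1 - alpha) quantile of that null. When
#' several tests are corrected jointly (\code{crossTestMax}), the
#' per-permutation maximum is taken across all supplied tests before the
#' quantile, mirroring the across-tests maximum-statistic correction.
#'
#' @param effects subjects x points matrix, or a list of such matrices
#'   for joint correction across tests.
#' @param adjacency "time" for 1-D time courses, or
#'   \code{list(dims =, conn =)} for grids (conn 4 for time x time,
#'   26 for voxels).
#' @param formingP cluster-forming p threshold (study default 0.001).
#' @param alpha cluster-level significance threshold (study default
#'   0.05).
#' @param nPerm number of permutations.
#' @param tail "one" or "two".
#' @param seed integer RNG seed.
#' @return a \linkS4class{ClusterResult} (or a list of them, one per
#'   test, sharing the joint null when \code{effects} is a list).
#' @export
clusterPermutation <- function(effects, adjacency = "time",
                               formingP = 0.001, alpha = 0.05,
                               nPerm = 1000, tail = c("one", "two"),
                               seed = 1) {
  tail <- match.arg(tail)
  assertNumber(formingP, "formingP", 0, 1)
  assertNumber(alpha, "alpha", 0, 1)
  assertCount(nPerm, "nPerm", min = 1)
  single <- !is.list(effects)
  if (single) effects <- list(effects)
  effects <- lapply(effects, as.matrix)
  n <- nrow(effects[[1]])
  signs <- withSeed(seed, {
    s <- matrix(sample(c(-1, 1), (nPerm - 1) * n, replace = TRUE),
                nPerm - 1, n)
    rbind(rep(1, n), s)
  })
  per_test <- lapply(effects, function(e) {
    null_means <- (signs %*% e) / n
    stat <- if (tail == "two") abs(null_means) else null_means
    thr <- apply(stat, 2, stats::quantile, probs = 1 - formingP,
                 type = 1)
    supra_null <- stat >= rep(thr, each = nPerm) - 1e-12
    max_sizes <- vapply(seq_len(nPerm), function(k) {
      comps <- clusterComponents(supra_null[k, ], adjacency)
      if (length(comps)) max(lengths(comps)) else 0
    }, numeric(1))
    obs_comps <- clusterComponents(supra_null[1, ], adjacency)
    list(thr = thr, max_sizes = max_sizes, obs = obs_comps)
  })
  null_max <- Reduce(pmax, lapply(per_test, `[[`, "max_sizes"))
  res <- lapply(per_test, function(pt) {
    sizes <- lengths(pt$obs)
    p <- vapply(sizes, function(s) mean(null_max >= s), numeric(1))
    crit <- stats::quantile(null_max, probs = 1 - alpha, type = 1)
    new("ClusterResult", clusters = pt$obs, clusterP = p,
        formingThreshold = pt$thr, nullMaxSizes = null_max,
        alpha = alpha, significant = sizes > crit)
  })
  if (single) res[[1]] else res
}

#' Conjunction of significance masks
#'
#' Logical AND across masks on the same grid: significant everywhere.
#'
#' @param masks list of logical vectors/arrays with identical
#'   dimensions.
#' @return logical mask.
#' @export
conjunctionMask <- function(masks) {
  if (!length(masks)) stopf("at least one mask is required")
  dims <- lapply(masks, function(m) dim(m) %||% length(m))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("grid mismatch: masks must share dimensions")
  Reduce(`&`, masks)
}
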