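test_that("noise normalization equalizes channel variances", {
  # one channel scaled 10x: residual variances even out after whitening
  times <- seq(0, 90, 10)
  gt <- makeGroundTruth(3, 6, 0.5, noiseSd = 1, seed = 1)
  ep <- simulateEpochs(gt, 20, 8, times = times, depictions = "photo",
                       noiseSd = 1, seed = 2)
  d <- dataArray(ep)
  d[, 3, ] <- d[, 3, ] * 10
  ep_scaled <- EpochSet(d, categoryLabels(ep), depictionLabels(ep),
                        times)
  nn <- noiseNormalize(ep_scaled)
  resid_var <- function(e) {
    d <- dataArray(e)
    for (cc in unique(categoryLabels(e))) {
      idx <- categoryLabels(e) == cc
      mu <- apply(d[idx, , , drop = FALSE], c(2, 3), mean)
      for (i in which(idx)) d[i, , ] <- d[i, , ] - mu
    }
    apply(d, 2, function(x) mean(x^2))
  }
  v_before <- resid_var(ep_scaled)
  v_after <- resid_var(nn)
  expect_gt(max(v_before) / min(v_before), 50)
  expect_lt(max(v_after) / min(v_after), 2)
})

test_that("whitening leaves already-white data nearly unchanged", {
  times <- seq(0, 40, 10)
  set.seed(3)
  d <- array(rnorm(200 * 6 * length(times)), c(200, 6, length(times)))
  ep <- EpochSet(d, rep(1:2, each = 100),
                 rep("photo", 200), times)
  nn <- noiseNormalize(ep)
  expect_lt(max(abs(dataArray(nn) - dataArray(ep))), 0.2)
  # and it is idempotent up to tolerance
  nn2 <- noiseNormalize(nn)
  expect_lt(max(abs(dataArray(nn2) - dataArray(nn))), 0.2)
})

test_that("supertrial construction partitions trials without reuse", {
  ep <- smallEpochs(nCat = 3, nTrials = 24, seed = 5)
  sts <- makeSupertrials(ep, groupSize = 2, nRepetitions = 3,
                         seed = 1)
  expect_length(sts, 3)
  for (st in sts)
    expect_true(all(table(categoryLabels(st)) == 12))
  # different assignments across repetitions
  expect_false(identical(dataArray(sts[[1]]), dataArray(sts[[2]])))
  # grand mean is preserved by averaging (linearity)
  expect_equal(mean(dataArray(sts[[1]])), mean(dataArray(ep)),
               tolerance = 1e-12)
  expect_error(makeSupertrials(ep, groupSize = 5), "divisible")
})

test_that("averaging identical trials returns the trial", {
  times <- seq(0, 20, 10)
  one <- array(rnorm(6 * 3), c(1, 6, 3))
  d <- array(0, c(4, 6, 3))
  for (i in 1:4) d[i, , ] <- one[1, , ]
  ep <- EpochSet(d, rep(1L, 4), rep("photo", 4), times)
  st <- makeSupertrials(ep, 2, 1, seed = 1)[[1]]
  expect_equal(dataArray(st)[1, , ], one[1, , ], tolerance = 1e-12)
})

test_that("time-resolved decoding equals the independent fold oracle", {
  toy <- toySupertrialSet()
  mine <- accuracyValues(pairwiseDecodeTimecourse(list(toy$set)))
  oracle <- kernlabPairwiseLOO(toy$x, toy$y)
  expect_equal(mine, oracle, tolerance = 1e-9)
  expect_lt(mine, 100)  # the planted outlier is misclassified
})

test_that("noise-free separable patterns decode perfectly in-window", {
  times <- seq(-50, 150, 10)
  gt <- makeGroundTruth(3, 8, 0.5, noiseSd = 0,
                        responseProfile =
                          defaultResponseProfile(times, 50, 40),
                        seed = 2)
  ep <- simulateEpochs(gt, 6, 10, times = times, noiseSd = 0.01,
                       depictions = "photo", seed = 3)
  st <- makeSupertrials(ep, 2, 1, seed = 4)
  tc <- pairwiseDecodeTimecourse(st)
  expect_equal(accuracyValues(tc)[timePoints(tc) == 50], 100)
  expect_equal(chanceLevel(tc), 50)
})

test_that("accuracy is invariant to consistent channel permutation", {
  ep <- smallEpochs(nCat = 3, nTrials = 6, times = seq(0, 60, 20),
                    seed = 9)
  st <- makeSupertrials(ep, 2, 1, seed = 1)
  perm <- sample(dim(dataArray(st[[1]]))[2])
  st_perm <- list(initialize(st[[1]],
                             data = dataArray(st[[1]])[, perm, ,
                                                       drop = FALSE]))
  expect_equal(accuracyValues(pairwiseDecodeTimecourse(st)),
               accuracyValues(pairwiseDecodeTimecourse(st_perm)))
})

test_that("ROI decoding matches exhaustive fold enumeration on a toy", {
  # 3 conditions x 2 runs x 2 voxels
  set.seed(11)
  b <- array(rnorm(3 * 2 * 2), c(2, 3, 2))
  b[, 1, ] <- b[, 1, ] + 3
  b[, 2, 2] <- b[, 2, 2] + 3
  bs <- BetaSet(b)
  mine <- pairwiseDecodeROI(bs)
  # oracle: enumerate runs and pairs with the independent classifier;
  # rows 1..3 are run 1's conditions, rows 4..6 run 2's
  x <- rbind(b[1, , ], b[2, , ])
  y <- rep(1:3, 2)
  pairs <- utils::combn(3, 2)
  orc <- mean(apply(pairs, 2, function(pr) {
    mean(vapply(1:2, function(r) {
      tr_rows <- pr + (2 - r) * 3
      te_rows <- pr + (r - 1) * 3
      fit <- kernlab::ksvm(x = x[tr_rows, , drop = FALSE],
                           y = factor(y[tr_rows]),
                           kernel = "vanilladot", kpar = list(),
                           C = 1, scaled = FALSE)
      mean(as.character(kernlab::predict(fit,
                                         x[te_rows, , drop = FALSE]))
           == as.character(y[te_rows]))
    }, numeric(1)))
  })) * 100
  expect_equal(mine, orc, tolerance = 1e-9)
})

test_that("noise-free identical runs decode at 100%", {
  gt <- makeGroundTruth(4, 8, 0.5, seed = 1)
  b <- simulateBetas(gt, nRuns = 3, nVoxels = 10, noiseSd = 0,
                     seed = 2)
  expect_equal(pairwiseDecodeROI(b), 100)
})

test_that("run-shuffled ROI labels decode at chance over simulations", {
  set.seed(21)
  accs <- vapply(1:100, function(s) {
    b <- array(rnorm(2 * 3 * 4), c(2, 3, 4))  # pure noise
    pairwiseDecodeROI(BetaSet(b))
  }, numeric(1))
  # 100 sims x 3 pairs x 2 runs x 2 decisions = 1200 decisions
  band <- qnorm(0.995) * sqrt(2500 / 1200)
  expect_lt(abs(mean(accs) - 50), band)
})

test_that("searchlight recovers a planted signal blob", {
  gt <- makeGroundTruth(4, 10, 0.5, seed = 1)
  bg <- simulateBetas(gt, nRuns = 3, grid = c(9, 9, 5),
                      blobCenter = c(2, 4, 2), blobRadius = 2,
                      noiseSd = 0.6, signalScale = 1, seed = 2)
  m <- searchlightDecode(bg, radiusVoxels = 2, smoothingFwhmMm = 0)
  pk <- which(accuracyValues(m) == max(accuracyValues(m), na.rm = TRUE),
              arr.ind = TRUE)[1, ] - 1
  expect_lte(sum((pk - c(2, 4, 2))^2), 2^2)
  # zero-signal grid stays near chance
  b0 <- simulateBetas(gt, nRuns = 3, grid = c(5, 5, 3),
                      blobCenter = c(2, 2, 1), blobRadius = 1,
                      noiseSd = 1, signalScale = 0, seed = 3)
  m0 <- searchlightDecode(b0, radiusVoxels = 2, smoothingFwhmMm = 5)
  v0 <- accuracyValues(m0)[m0@mask]
  expect_lt(abs(mean(v0) - 50), 6)
})

test_that("cross-decoding on identical data equals within-decoding", {
  ep <- smallEpochs(nCat = 3, nTrials = 6, times = seq(0, 40, 20),
                    seed = 13)
  st <- makeSupertrials(ep, 2, 2, seed = 2)
  within <- accuracyValues(pairwiseDecodeTimecourse(st))
  crossed <- accuracyValues(crossDecode(st, st, mode = "timecourse"))
  expect_equal(crossed, within, tolerance = 1e-12)
  # direction symmetry by construction
  ep2 <- smallEpochs(nCat = 3, nTrials = 6, times = seq(0, 40, 20),
                     depictions = "drawing", seed = 17)
  st2 <- makeSupertrials(subsetEpochs(ep2, "drawing"), 2, 2, seed = 2)
  expect_equal(accuracyValues(crossDecode(st, st2, "timecourse")),
               accuracyValues(crossDecode(st2, st, "timecourse")),
               tolerance = 1e-12)
  expect_error(crossDecode(st, st[1], "timecourse"), "repetitions")
})

test_that("temporal generalization diagonal equals the time course", {
  ep <- smallEpochs(nCat = 3, nTrials = 6, times = seq(-20, 80, 20),
                    seed = 19)
  st <- makeSupertrials(ep, 2, 1, seed = 3)
  tg <- temporalGeneralization(st)
  tc <- pairwiseDecodeTimecourse(st)
  expect_equal(diag(accuracyValues(tg)), accuracyValues(tc),
               tolerance = 1e-12)
})

test_that("a sign-reversing pattern generalizes below chance across the flip", {
  # constant geometry that flips sign at t = 3: train-early/test-late
  # should be systematically wrong
  set.seed(23)
  pat <- matrix(rnorm(3 * 8), 3)
  times <- seq(0, 50, 10)
  flip <- ifelse(times < 30, 1, -1)
  d <- array(0, c(12, 8, length(times)))
  cat_lab <- rep(1:3, each = 4)
  for (i in 1:12) for (t in seq_along(times))
    d[i, , t] <- flip[t] * pat[cat_lab[i], ] + rnorm(8, 0, 0.3)
  st <- list(new("SupertrialSet", data = d,
                 category = as.integer(cat_lab), times = times,
                 groupSize = 2L, assignmentRepetition = 1L))
  tg <- accuracyValues(temporalGeneralization(st))
  early <- times < 30; late <- !early
  expect_gt(mean(diag(tg)), 90)
  expect_lt(mean(tg[early, late]), 20)
})

test_that("decoding accuracy does not increase with noise", {
  sds <- c(0.3, 1.5, 6)
  acc <- vapply(sds, function(ns) {
    mean(vapply(1:5, function(s) {
      gt <- makeGroundTruth(3, 8, 0.5, seed = s)
      ep <- simulateEpochs(gt, 6, 10, times = c(90, 100, 110),
                           depictions = "photo", noiseSd = ns,
                           seed = s + 50)
      mean(accuracyValues(pairwiseDecodeTimecourse(
        makeSupertrials(subsetEpochs(ep, "photo"), 2, 1,
                        seed = s))))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) <= 1e-9))
})
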