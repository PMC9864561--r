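test_that("shared fraction controls between-depiction pattern overlap", {
  # extremes
  gt1 <- makeGroundTruth(6, 20, sharedFraction = 1, seed = 3)
  expect_equal(gt1@patterns$photo, gt1@patterns$sketch)
  m0 <- mean(vapply(1:60, function(s)
    meanPatternCor(makeGroundTruth(6, 20, 0, seed = s)), numeric(1)))
  expect_lt(abs(m0), 0.03)
  # calibrated midpoint: study-sized patterns, Monte-Carlo over seeds
  m05 <- mean(vapply(1:100, function(s)
    meanPatternCor(makeGroundTruth(48, 300, 0.5, seed = s)),
    numeric(1)))
  expect_lt(abs(m05 - 0.5), 0.05)
})

test_that("pattern correlation is monotone in sharedFraction", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  m <- vapply(grid, function(sf)
    mean(vapply(1:100, function(s)
      meanPatternCor(makeGroundTruth(5, 40, sf, seed = s)),
      numeric(1))), numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("ground truth rejects invalid shared fractions", {
  expect_error(makeGroundTruth(4, 10, sharedFraction = 1.2),
               "sharedFraction")
  expect_error(makeGroundTruth(4, 10, sharedFraction = -0.1),
               "sharedFraction")
})

test_that("simulated epochs have the designed cell structure", {
  gt <- makeGroundTruth(3, 8, 0.5, seed = 1)
  ep <- simulateEpochs(gt, nTrialsPerCell = 24, nChannels = 10,
                       times = seq(-100, 100, 10), seed = 2)
  cells <- table(categoryLabels(ep), depictionLabels(ep))
  expect_true(all(cells == 24))
  expect_error(simulateEpochs(gt, nTrialsPerCell = 7), "even")
})

test_that("epoch signal follows the response profile", {
  times <- seq(-100, 300, 10)
  gt <- makeGroundTruth(3, 8, 0.5, noiseSd = 0,
                        responseProfile =
                          defaultResponseProfile(times, peak_ms = 100),
                        seed = 1)
  ep <- simulateEpochs(gt, 2, 10, times = times, noiseSd = 0,
                       depictions = "photo", seed = 2)
  energy <- apply(dataArray(ep)^2, 3, sum)
  expect_equal(timePoints(ep)[which.max(energy)], 100)
  expect_true(all(dataArray(ep)[, , times < 0] == 0))
  # zero profile and zero noise give all-zero epochs
  gt0 <- makeGroundTruth(3, 8, 0.5, noiseSd = 0,
                         responseProfile = data.frame(
                           time_ms = times, amplitude = 0), seed = 1)
  ep0 <- simulateEpochs(gt0, 2, 10, times = times, noiseSd = 0,
                        depictions = "photo", seed = 2)
  expect_true(all(dataArray(ep0) == 0))
})

test_that("generators are bit-reproducible given the seed", {
  gt <- makeGroundTruth(4, 10, 0.5, seed = 7)
  a <- simulateEpochs(gt, 4, 8, times = seq(0, 100, 10), seed = 11)
  b <- simulateEpochs(gt, 4, 8, times = seq(0, 100, 10), seed = 11)
  d <- simulateEpochs(gt, 4, 8, times = seq(0, 100, 10), seed = 12)
  expect_identical(dataArray(a), dataArray(b))
  expect_false(identical(dataArray(a), dataArray(d)))
})

test_that("simulated betas mirror the run x condition x voxel design", {
  gt <- makeGroundTruth(48, 30, 0.5, seed = 1)
  b <- simulateBetas(gt, nRuns = 4, nVoxels = 20, noiseSd = 0.5,
                     seed = 2)
  expect_equal(dim(dataArray(b)), c(4, 48, 20))
  b0 <- simulateBetas(gt, nRuns = 3, nVoxels = 10, noiseSd = 0,
                      seed = 3)
  expect_equal(dataArray(b0)[1, , ], dataArray(b0)[3, , ])
  expect_error(simulateBetas(gt, grid = c(4, 4, 4), blobRadius = 3),
               "grid smaller than blob")
})

test_that("trial sequences reproduce the session design arithmetic", {
  fmri <- simulateTrialSequence(nRuns = 4, perRun = 2, nImages = 48,
                                stimMs = 500, isiMs = 2500,
                                catchIsiMs = 2500, seed = 1)
  sf <- sequenceSummary(fmri)
  expect_true(all(sf$presentations_per_image == 8))
  expect_equal(sf$expected_experimental_ms, 3000)
  meg <- simulateTrialSequence(nRuns = 3, perRun = 8, nImages = 48,
                               seed = 2)
  sm <- sequenceSummary(meg)
  expect_true(all(sm$presentations_per_image == 24))
  expect_equal(sm$expected_experimental_ms, 800)
  expect_equal(sm$expected_catch_ms, 1600)
  # no immediate stimulus repetition within a run
  for (r in unique(meg$run)) {
    img <- meg$image[meg$run == r & meg$type == "experimental"]
    expect_false(any(img[-1] == img[-length(img)]))
  }
  # proportion mode hits the requested catch fraction
  prop <- simulateTrialSequence(nRuns = 2, perRun = 4, nImages = 48,
                                catchMode = "proportion",
                                catchProportion = 0.2, seed = 3)
  expect_lt(abs(sequenceSummary(prop)$catch_fraction - 0.2), 0.03)
})

test_that("the 1000 Hz epoch grid downsamples to 111 points at 100 Hz", {
  expect_length(downsampleTimes(seq(-100, 1001, by = 1), 10), 111)
  expect_length(defaultEpochTimes(), 111)
})
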