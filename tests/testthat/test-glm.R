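test_that("the HRF library spans unit-peak kernels with 4-8 s peaks", {
  lib <- hrfLibrary(trS = 1.5)
  expect_equal(ncol(lib@kernels), 20)
  expect_equal(apply(lib@kernels, 2, max), rep(1, 20))
  peak_s <- lib@times[apply(lib@kernels, 2, which.max)]
  expect_true(all(peak_s >= 3 & peak_s <= 9))
  expect_true(all(diff(peak_s) >= 0))
})

test_that("design columns are shifted HRFs and linear in events", {
  lib <- hrfLibrary(trS = 1.5)
  h <- lib@kernels[, 5]
  # a single short event at a scan boundary: the column tracks the HRF
  ev1 <- data.frame(onset = 15, duration = 0.1, condition = "a")
  x1 <- buildDesign(ev1, h, nScans = 60, trS = 1.5)
  expect_equal(colnames(x1), "a")
  shifted <- c(rep(0, 10), h, rep(0, 60))[1:60]
  expect_gt(cor(x1[, 1], shifted), 0.995)
  # two non-overlapping events sum (linearity)
  ev2 <- data.frame(onset = c(15, 45), duration = 0.1,
                    condition = "a")
  x2 <- buildDesign(ev2, h, nScans = 60, trS = 1.5)
  ev2b <- data.frame(onset = 45, duration = 0.1, condition = "a")
  x2b <- buildDesign(ev2b, h, nScans = 60, trS = 1.5)
  expect_equal(x2[, 1], x1[, 1] + x2b[, 1], tolerance = 1e-10)
  # one column per condition
  ev48 <- data.frame(onset = seq(2, 96, 2), duration = 0.5,
                     condition = sprintf("c%02d", 1:48))
  expect_equal(ncol(buildDesign(ev48, h, nScans = 120, trS = 1.5)),
               48)
  # validation
  expect_error(buildDesign(data.frame(onset = 500, duration = 1,
                                      condition = "a"),
                           h, 60, 1.5), "scan duration")
  expect_error(buildDesign(data.frame(onset = c(10, 10.2),
                                      duration = 1,
                                      condition = c("a", "b")),
                           h, 60, 1.5), "overlap")
})

test_that("noise-free data recovers the generating HRF and betas", {
  lib <- hrfLibrary(trS = 1.5)
  ev <- data.frame(onset = seq(5, 160, 15), duration = 0.5,
                   condition = rep(c("a", "b"), length.out = 11))
  tb <- matrix(c(2, 1, 0.5, 3, -1, 2), 2, 3)
  y <- simulateBold(ev, hrfIndex = 7, trueBetas = tb, noiseSd = 0,
                    nScans = 130, seed = 1)
  fit <- fitHrfSelectedGlm(y, ev, lib)
  expect_true(all(fit@chosenHrfIndex == 7))
  expect_equal(unname(fit@betas), tb, tolerance = 1e-6)
  # two voxel populations with different HRFs are recovered per voxel
  y2 <- simulateBold(ev, hrfIndex = c(3, 15, 3, 15),
                     trueBetas = matrix(1:8, 2, 4), noiseSd = 0,
                     nScans = 130, seed = 2)
  fit2 <- fitHrfSelectedGlm(y2, ev, lib)
  expect_equal(fit2@chosenHrfIndex, c(3L, 15L, 3L, 15L))
  # zero signal gives near-zero betas
  y0 <- simulateBold(ev, hrfIndex = 7,
                     trueBetas = matrix(0, 2, 2), noiseSd = 0.2,
                     nScans = 130, seed = 3)
  fit0 <- fitHrfSelectedGlm(y0, ev, lib)
  expect_lt(max(abs(fit0@betas)), 0.3)
})

test_that("beta recovery error vanishes as noise decreases", {
  lib <- hrfLibrary(trS = 1.5)
  ev <- data.frame(onset = seq(5, 160, 15), duration = 0.5,
                   condition = rep(c("a", "b"), length.out = 11))
  tb <- matrix(c(2, 1), 2, 1)
  errs <- vapply(c(1, 0.1, 0.01), function(ns) {
    y <- simulateBold(ev, 7, tb, noiseSd = ns, nScans = 130,
                      seed = 4)
    max(abs(fitHrfSelectedGlm(y, ev, lib)@betas - tb))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("HRF selection succeeds on most voxels at moderate SNR", {
  lib <- hrfLibrary(trS = 1.5)
  ev <- data.frame(onset = seq(5, 280, 12), duration = 0.5,
                   condition = rep(c("a", "b"), length.out = 23))
  set.seed(5)
  idx <- sample(20, 30, replace = TRUE)
  tb <- matrix(5, 2, 30)  # strong response: SNR >= 5 at noiseSd below
  y <- simulateBold(ev, idx, tb, noiseSd = 0.5, nScans = 220,
                    seed = 6)
  fit <- fitHrfSelectedGlm(y, ev, lib)
  # neighbouring library kernels are near-duplicates; selection within
  # one index counts as a hit
  expect_gte(mean(abs(fit@chosenHrfIndex - idx) <= 1), 0.95)
})

test_that("rank-deficient designs name the collinear columns", {
  lib <- hrfLibrary(trS = 1.5)
  ev <- data.frame(onset = c(10, 40), duration = 0.5,
                   condition = c("a", "b"))
  y <- matrix(rnorm(60 * 2), 60, 2)
  x_dup <- buildDesign(ev, lib@kernels[, 1], 60, 1.5)[, 1]
  expect_error(fitHrfSelectedGlm(y, ev, lib,
                                 nuisance = cbind(dup = x_dup)),
               "collinear")
})

test_that("outlier volumes are flagged and interpolated", {
  set.seed(7)
  bold <- matrix(rnorm(200 * 6, 100, 0.5), 200, 6)
  clean <- detectOutlierVolumes(bold)
  expect_length(clean$outliers, 0)
  # a spike whose scaled framewise difference lands above 30-fold
  spiked <- bold
  spiked[20, ] <- spiked[20, ] + 70 * mean(abs(diff(bold)))
  res <- detectOutlierVolumes(spiked)
  expect_gt(max(res$scaledDiff), 30)
  expect_true(all(c(20, 21) %in% res$outliers))
  # linear interpolation across the flagged block (19 -> 22)
  interp <- spiked[19, ] + (spiked[22, ] - spiked[19, ]) / 3
  expect_equal(res$interpolated[20, ], interp, tolerance = 1e-10)
  # displacement of 0.6 mm on one axis flags the volume
  mp <- matrix(0, 200, 6)
  mp[30, 2] <- 0.6
  res2 <- detectOutlierVolumes(bold, motionParams = mp)
  expect_true(30 %in% res2$outliers)
  expect_error(detectOutlierVolumes(bold[1:2, ]), "3 volumes")
})

test_that("noise components recover shared structure and are orthonormal", {
  set.seed(8)
  drift <- sin(seq(0, 6 * pi, length.out = 80))
  noise_vox <- sapply(1:15, function(i)
    drift * runif(1, 0.5, 2) + rnorm(80, 0, 0.1))
  comps <- extractNoiseComponents(noise_vox, 3)
  expect_gt(abs(cor(comps[, 1], drift)), 0.98)
  expect_equal(crossprod(comps), diag(3), tolerance = 1e-10)
  expect_error(extractNoiseComponents(noise_vox[, 1:2], 5),
               "at least")
  # rank limit
  rank1 <- outer(drift, rep(1, 4))
  expect_error(extractNoiseComponents(rank1, 2), "rank")
})

test_that("nuisance sets include motion derivatives", {
  mp <- matrix(rnorm(30 * 6), 30, 6)
  nui <- nuisanceRegressors(noiseComponents = matrix(rnorm(30 * 2),
                                                     30, 2),
                            motionParams = mp)
  expect_equal(ncol(nui), 2 + 6 * 3)
  expect_equal(nrow(nui), 30)
})
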