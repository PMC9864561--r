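test_that("sign-permutation p-values match exhaustive enumeration", {
  set.seed(7)
  e <- matrix(rnorm(5 * 4, mean = 0.4), 5, 4)
  res <- signPermutationTest(e, nPerm = 32, tail = "one")
  # independent oracle: enumerate all 2^5 sign patterns by hand
  signs <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1),
                                 s3 = c(-1, 1), s4 = c(-1, 1),
                                 s5 = c(-1, 1)))
  obs <- colMeans(e)
  oracle <- vapply(seq_len(ncol(e)), function(j) {
    null <- drop(signs %*% e[, j]) / 5
    mean(null >= obs[j] - 1e-12)
  }, numeric(1))
  expect_equal(pValues(res), oracle)
  expect_equal(res@nPermutations, 32L)
  # two-sided variant against the same oracle
  res2 <- signPermutationTest(e, nPerm = 32, tail = "two")
  oracle2 <- vapply(seq_len(ncol(e)), function(j) {
    null <- abs(drop(signs %*% e[, j]) / 5)
    mean(null >= abs(obs[j]) - 1e-12)
  }, numeric(1))
  expect_equal(pValues(res2), oracle2)
})

test_that("sign-permutation edge cases behave", {
  expect_equal(pValues(signPermutationTest(matrix(0, 6, 2),
                                           nPerm = 64)),
               c(1, 1))
  set.seed(1)
  res <- signPermutationTest(matrix(rnorm(4 * 3, 5, 0.1), 4, 3),
                             nPerm = 16)
  expect_true(all(pValues(res) >= 1 / 16))
  expect_error(signPermutationTest(matrix(0, 1, 2)), "2 subjects")
})

test_that("BH FDR reproduces the hand step-up computation", {
  expect_equal(fdrBH(c(0.001, 0.02, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(fdrBH(rep(1, 5)), rep(FALSE, 5))
  expect_true(fdrBH(0.04, q = 0.05))
  expect_false(fdrBH(0.06, q = 0.05))
  # FDR rejections are a superset of Bonferroni rejections
  set.seed(2)
  p <- c(runif(30), runif(10, 0, 1e-3))
  expect_true(all(fdrBH(p, 0.05)[p <= 0.05 / length(p)]))
  # mask is monotone in q
  expect_true(all(fdrBH(p, 0.01) <= fdrBH(p, 0.1)))
})

test_that("cluster correction recovers a planted contiguous effect", {
  set.seed(3)
  n <- 12; np <- 40
  eff <- matrix(rnorm(n * np, 0, 1), n, np)
  planted <- 15:24
  eff[, planted] <- eff[, planted] + 2
  cl <- clusterPermutation(eff, "time", formingP = 0.01,
                           alpha = 0.05, nPerm = 500, seed = 4)
  sig <- clusters(cl)[cl@significant]
  expect_length(sig, 1)
  expect_true(all(sig[[1]] %in% planted))
  expect_gte(length(sig[[1]]), 8)
})

test_that("empty suprathreshold sets yield an empty result, not an error", {
  set.seed(5)
  eff <- matrix(rnorm(8 * 20), 8, 20)
  cl <- clusterPermutation(eff, "time", formingP = 0.001,
                           alpha = 0.05, nPerm = 200, seed = 6)
  expect_true(length(clusters(cl)) == 0 || !any(cl@significant))
})

test_that("across-test maximum correction is at least as strict", {
  set.seed(7)
  effs <- lapply(1:3, function(i) {
    e <- matrix(rnorm(10 * 30), 10, 30)
    e[, 10:18] <- e[, 10:18] + 1.5
    e
  })
  joint <- clusterPermutation(effs, "time", formingP = 0.05,
                              alpha = 0.05, nPerm = 300, seed = 8)
  singles <- lapply(effs, clusterPermutation, adjacency = "time",
                    formingP = 0.05, alpha = 0.05, nPerm = 300,
                    seed = 8)
  joint_crit <- quantile(joint[[1]]@nullMaxSizes, 0.95, type = 1)
  for (s in singles)
    expect_gte(joint_crit, quantile(s@nullMaxSizes, 0.95, type = 1))
})

test_that("grid adjacency clusters components correctly", {
  # 4-connectivity on a 3x3 grid: an L-shape is one cluster, a
  # diagonally placed point stays separate
  supra <- matrix(FALSE, 3, 3)
  supra[1, 1] <- supra[1, 2] <- supra[2, 2] <- TRUE
  supra[3, 3] <- TRUE
  comps <- mvpafusion:::clusterComponents(as.vector(supra),
                                          list(dims = c(3, 3),
                                               conn = 4))
  sizes <- sort(lengths(comps))
  expect_equal(sizes, c(1, 3))
  # 26-connectivity joins diagonal voxels in 3-D
  supra3 <- array(FALSE, c(2, 2, 2))
  supra3[1, 1, 1] <- TRUE; supra3[2, 2, 2] <- TRUE
  comps3 <- mvpafusion:::clusterComponents(as.vector(supra3),
                                           list(dims = c(2, 2, 2),
                                                conn = 26))
  expect_length(comps3, 1)
  comps6 <- mvpafusion:::clusterComponents(as.vector(supra3),
                                           list(dims = c(2, 2, 2),
                                                conn = 6))
  expect_length(comps6, 2)
})

test_that("conjunction masks are elementwise AND", {
  m1 <- c(TRUE, TRUE, FALSE); m2 <- c(TRUE, FALSE, FALSE)
  expect_equal(conjunctionMask(list(m1, m1)), m1)
  expect_equal(conjunctionMask(list(m1, !m1)), rep(FALSE, 3))
  set.seed(9)
  r1 <- runif(20) > 0.5; r2 <- runif(20) > 0.5; r3 <- runif(20) > 0.5
  expect_equal(conjunctionMask(list(r1, r2, r3)), r1 & r2 & r3)
  expect_error(conjunctionMask(list(m1, c(TRUE, FALSE))),
               "grid mismatch")
})

test_that("identical noiseless curves give a zero-width CI at the peak", {
  times <- seq(-100, 400, 10)
  curve <- exp(-0.5 * ((times - 100) / 50)^2)
  tc <- matrix(rep(curve, 4), 4, byrow = TRUE)
  ci <- bootstrapPeak(tc, times, nBoot = 200, seed = 1)
  expect_equal(peakLatency(ci), 100)
  expect_equal(unname(peakCI(ci)), c(100, 100))
})

test_that("window restriction changes the detected peak", {
  times <- seq(-100, 450, 10)
  # global max late (post-stimulus artifact), in-window peak at 100 ms
  curve <- exp(-0.5 * ((times - 100) / 40)^2) +
    2 * exp(-0.5 * ((times - 440) / 10)^2)
  tc <- matrix(rep(curve, 3), 3, byrow = TRUE)
  full <- bootstrapPeak(tc, times, nBoot = 50, seed = 2)
  restricted <- bootstrapPeak(tc, times, nBoot = 50,
                              window = c(-100, 400), seed = 2)
  expect_equal(peakLatency(full), 440)
  expect_equal(peakLatency(restricted), 100)
})

test_that("flat curves trigger a tie warning", {
  tc <- matrix(1, 3, 10)
  expect_warning(bootstrapPeak(tc, 1:10, nBoot = 10, seed = 1),
                 "flat")
})

test_that("peak-difference CI behaves for identical and shifted curves", {
  times <- seq(-100, 400, 10)
  a <- plantedPeakCurves(10, times, peak = 100, jitterSd = 10,
                         noiseSd = 0.02, seed = 3)
  same <- bootstrapPeakDifference(a, a, times, nBoot = 300, seed = 4)
  expect_equal(same$difference, 0)
  expect_false(same$significant)
  b <- plantedPeakCurves(10, times, peak = 180, jitterSd = 10,
                         noiseSd = 0.02, seed = 5)
  shifted <- bootstrapPeakDifference(a, b, times, nBoot = 300,
                                     seed = 6)
  expect_true(shifted$significant)
  expect_lt(shifted$ciHigh, 0)
  # antisymmetry under a shared seed
  rev <- bootstrapPeakDifference(b, a, times, nBoot = 300, seed = 6)
  expect_equal(rev$samples, -shifted$samples)
})

test_that("TOST equivalence follows the bounds", {
  set.seed(8)
  a <- rnorm(500, 100, 3)
  # identical samples: equivalent at any positive bound
  expect_lt(tostEquivalence(a, a, boundsMs = 5)$p, 1e-6)
  # mean difference far outside the bounds
  b <- a + 50
  expect_gt(tostEquivalence(a, b, boundsMs = 5)$p, 0.99)
  # 5 ms difference: equivalent within 10 ms, not within 2 ms
  d5 <- a + 5 + rnorm(500, 0, 1)
  expect_lt(tostEquivalence(a, d5, boundsMs = 10)$p, 0.01)
  expect_gt(tostEquivalence(a, d5, boundsMs = 2)$p, 0.5)
  expect_error(tostEquivalence(a, b), "bounds")
  # subject-level variant
  subj_a <- rnorm(12, 100, 2); subj_b <- subj_a + rnorm(12, 0, 1)
  expect_lt(tostEquivalence(subj_a, subj_b, boundsMs = 5,
                            type = "subjects")$p, 0.05)
})
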