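# Shared fixtures, built in code at test time.

# Small ground truth + epochs used across decoding tests.
smallEpochs <- function(nCat = 4, nFeat = 10, nChan = 12,
                        nTrials = 8, sf = 0.5, noiseSd = 1,
                        times = seq(-100, 200, 10),
                        depictions = "photo", seed = 1) {
  gt <- makeGroundTruth(nCat, nFeat, sf,
                        responseProfile = defaultResponseProfile(times),
                        seed = seed)
  simulateEpochs(gt, nTrials, nChan, times = times,
                 depictions = depictions, noiseSd = noiseSd,
                 seed = seed + 1)
}

# A fixed separable two-channel toy of 3 categories x 4 supertrials at
# one time point, with one supertrial planted far on the wrong side so
# the leave-one-out accuracy is informative (not 100%).
toySupertrialSet <- function() {
  set.seed(42)
  means <- rbind(c(0, 0), c(4, 0), c(0, 4))
  x <- do.call(rbind, lapply(1:3, function(cc)
    sweep(matrix(rnorm(8, 0, 0.2), 4, 2), 2, means[cc, ], "+")))
  x[2, ] <- c(7, 0)
  y <- rep(1:3, each = 4)
  list(x = x, y = y,
       set = new("SupertrialSet", data = array(x, c(12, 2, 1)),
                 category = as.integer(y), times = 0,
                 groupSize = 2L, assignmentRepetition = 1L))
}

# Independent fold-enumeration oracle: leave one item per class out,
# classify with kernlab's linear SVM (C = 1), average over folds and
# pairs. Used to cross-check the e1071-based pipeline.
kernlabPairwiseLOO <- function(x, y) {
  cats <- sort(unique(y))
  pairs <- utils::combn(cats, 2)
  accs <- apply(pairs, 2, function(pr) {
    ia <- which(y == pr[1]); ib <- which(y == pr[2])
    nf <- min(length(ia), length(ib))
    mean(vapply(seq_len(nf), function(k) {
      tr <- c(ia[-k], ib[-k]); te <- c(ia[k], ib[k])
      fit <- kernlab::ksvm(x = x[tr, , drop = FALSE],
                           y = factor(y[tr]), kernel = "vanilladot",
                           kpar = list(), C = 1, scaled = FALSE)
      mean(as.character(kernlab::predict(fit, x[te, , drop = FALSE])) ==
             as.character(y[te]))
    }, numeric(1)))
  })
  mean(accs) * 100
}

# Mean between-depiction pattern correlation of a GroundTruth.
meanPatternCor <- function(gt) {
  p <- gt@patterns
  combos <- utils::combn(names(p), 2)
  mean(apply(combos, 2, function(cc) {
    mean(vapply(seq_len(nrow(p[[1]])), function(i)
      cor(p[[cc[1]]][i, ], p[[cc[2]]][i, ]), numeric(1)))
  }))
}

# Subject time courses with a planted peak and between-subject latency
# jitter, for bootstrap CI tests.
plantedPeakCurves <- function(nSubj = 16, times = seq(-100, 400, 10),
                              peak = 100, jitterSd = 30,
                              noiseSd = 0.05, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(nSubj), function(i) {
    pk <- peak + rnorm(1, 0, jitterSd)
    exp(-0.5 * ((times - pk) / 60)^2) + rnorm(length(times), 0, noiseSd)
  }, numeric(length(times))))
}
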