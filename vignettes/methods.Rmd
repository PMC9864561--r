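---
title: "Methods: spatiotemporal decoding, fusion, and their verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal decoding, fusion, and their verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpafusion)
```

This vignette documents the models and procedures the package
implements, the choices made where the design was genuinely open, and
what the synthetic test bed does and does not establish about real
data.

## The analysis model

The package targets experiments in which the same condition set (here:
object categories shown in several depiction types — photographs,
detailed drawings, abstract sketches) is measured with MEG and fMRI in
separate sessions. Three complementary read-outs are implemented.

**Pairwise decoding.** Category information is quantified as the mean
leave-one-out accuracy of linear SVMs over all unordered condition
pairs, so chance is always 50% regardless of the number of conditions.
On the MEG side the classifier sees channel patterns at one time point;
trials are first averaged in pairs into *supertrials*
(`makeSupertrials`), which trades trial count for signal-to-noise: with
24 trials per condition this yields 12 supertrials, 12
leave-one-supertrial-per-class-out folds, and the whole assignment is
re-randomized 5 times (`nRepetitions`) with accuracies averaged. On the
fMRI side the classifier sees run-wise beta patterns with
leave-one-run-out folds, either over an ROI (`pairwiseDecodeROI`) or a
searchlight sphere of radius 4 voxels swept over the grid
(`searchlightDecode`), whose accuracy map may be smoothed with a 5 mm
FWHM Gaussian afterwards.

**Cross-decoding and temporal generalization.** `crossDecode` trains on
one stimulus family and tests on the other with the same fold
structure, averaging both train/test directions; equality with
within-family decoding indicates an invariant format, a deficit
indicates tolerance without invariance. `temporalGeneralization` trains
at each time point and tests at all others; its diagonal reproduces the
time-resolved decoding exactly when folds are shared, which the test
suite asserts to machine precision.

**RSA fusion.** `computeRDM` builds representational dissimilarity
matrices as 1 − Pearson *r* between condition patterns (run- or
trial-averaged first), `megRDMSeries` produces one RDM per time point,
and `fusionTimecourse` correlates the lower triangle of each MEG RDM
with an ROI's fMRI RDM (Pearson; Spearman available in
`correlateRDMs` as a robustness check). A region's fusion curve peaks
when its representational geometry is expressed in the MEG signal, so
peak latencies order processing stages across regions. The lower
triangle is extracted in row-major order ((2,1), (3,1), (3,2), ...);
only consistency matters for correlations, but the order is fixed and
documented because results must be reproducible across tools.

## Inferential layer

All group inference is nonparametric, treating subjects as the unit:

- `signPermutationTest` flips the sign of subject-level effects
  (effects must be pre-centered on the null, e.g. accuracy − 50). The
  observed permutation is always a member of the null, so the smallest
  attainable p is 1/nPerm; with few subjects the test enumerates all
  2^n sign patterns and is exact.
- `clusterPermutation` controls family-wise error over time points,
  voxels, or train × test cells via the null distribution of the
  maximum cluster *size* (count of suprathreshold points). Adjacency is
  consecutive samples in time, 26-connectivity for voxel grids, and
  4-connectivity for time × time matrices. When several tests are
  corrected jointly the per-permutation maximum is taken across tests,
  which makes the criterion uniformly at least as strict as any
  single-test threshold.
- `bootstrapPeak` resamples subjects with replacement and reports the
  95% CI of the peak latency as mean ± 1.96 SD of the bootstrap peak
  distribution; `bootstrapPeakDifference` applies the same resample to
  both conditions (paired) and flags significance when the difference
  CI excludes zero. Peak ties break to the earliest sample — latency
  comparisons depend on this, so it is fixed rather than configurable.
  Peak windows may be restricted when a curve's global maximum lies
  outside the epoch of scientific interest.
- `tostEquivalence` runs two one-sided tests against ± bound. Bounds
  encode a scientific judgment about what "equivalent" means and are
  therefore mandatory arguments, never defaulted. Because a bootstrap
  distribution's SD already estimates the estimator's standard error,
  the bootstrap variant uses a z statistic without the 1/sqrt(n)
  factor; subject-level samples use a paired t.

## First-level GLM and gaze QC

`hrfLibrary` generates 20 double-gamma kernels spanning time-to-peak
values of about 4–8 s with covarying undershoot depth, each normalized
to unit peak. This parameterized family replaces an external kernel
file; `hrfLibrary(kernels = ...)` accepts a custom matrix for users who
have one. `fitHrfSelectedGlm` fits the GLM once per kernel and keeps,
per voxel, the betas of the kernel with the minimum mean squared
residual — a per-voxel HRF approximation that does not bias group
statistics because selection never sees the hypothesis. Outlier
screening (`detectOutlierVolumes`) operates per volume on
voxel-aggregated framewise intensity differences scaled by their
series mean (threshold 30-fold) and on per-axis framewise displacement
(0.5 mm); flagged volumes are linearly interpolated, with
nearest-neighbor extension at series edges.

Gaze QC follows the velocity-threshold microsaccade algorithm: a
5-sample moving-window differentiator, per-axis elliptic thresholds at
λ = 6 times a median-based velocity SD, minimum duration 3 samples.
λ and the duration are exposed because the literature varies; the
defaults are the common choice. Traces are treated monocularly. The
slow-drift high-pass is implemented as first-order (linear) detrending
per epoch (`detrendGaze`). Epochs with movements above 3° cannot have
landed on the stimulus and are dropped; retained trials are flagged
on-stimulus above 1.5°; subjects exceed the exclusion criterion when
strictly more than 5% of experimental trials are flagged.

## The synthetic test bed

`makeGroundTruth` draws per-depiction category patterns as
√s·common + √(1−s)·specific with iid standard-normal components, so the
expected between-depiction pattern correlation equals `sharedFraction`
(s). This single dial reproduces the study-relevant contrast: s = 1
makes cross-decoding match within-decoding, s = 0 drives cross-decoding
to chance while within-decoding stays high. Epochs are
profile(t) · (mixing · pattern) + noise, with an orthonormalized random
channel mixing (signal energy comparable across seeds) and a
transient Gaussian response profile peaking at 100 ms that is zero
before stimulus onset. The default grid is −100..1000 ms at 100 Hz
(111 points), the grid that results from segmenting −100..1001 ms at
1000 Hz and decimating by 10. Noise is iid Gaussian by default; a
channel-covariance mode (`channelCov = "random"`) draws spatially
correlated noise to exercise `noiseNormalize`. Beta generators place
signal either in every ROI voxel or in a compact spherical blob inside
a null grid, giving searchlight recovery tests a known target.
`simulateTwoStageEpochs` injects two geometries at two latencies to
test fusion peak ordering, and `simulateGaze` plants minimum-jerk
saccades with main-sequence durations (21 ms + 2.2 ms/°) whose peak
velocities clear the detector threshold at realistic noise levels
(0.01° positional SD).

What the generators deliberately do not emulate: MEG forward physics
(leadfields, correlated sensor noise topographies beyond the optional
random covariance), BOLD autocorrelation and physiological noise
spectra, saccadic oscillations or overshoot, and between-subject
anatomy. Passing tests therefore certify the *algorithms* — fold
bookkeeping, chance levels, calibration of the inference, parameter
recovery under the stated noise model — not performance on real
recordings.

## Numerical choices

- **SVM regularization.** C = 1 throughout, no hyperparameter search:
  pairwise linear decoding on few, high-dimensional patterns is
  insensitive to C over orders of magnitude, and a fixed value keeps
  results seed-stable. Non-convergent folds (not observed with libsvm
  in practice, but guarded) are excluded from averages, never imputed
  as chance.
- **Noise normalization** estimates the channel covariance from
  per-cell, per-time-point residuals pooled over trials and time, with
  Ledoit–Wolf shrinkage toward a scaled identity, and whitens by the
  inverse matrix square root. It is applied once to the whole epoch
  set before supertrial construction rather than refit inside every
  training fold: the covariance does not use test labels, refitting
  per fold multiplies cost by folds × pairs × repetitions, and the
  chance-calibration suite confirms the one-shot variant introduces no
  optimistic bias.
- **Supertrial order.** Normalization precedes averaging
  (normalize-then-average); since whitening is linear, the alternative
  order differs only through the covariance estimate.
- **Degenerate inputs.** Zero-variance condition patterns are an error
  naming the condition (an RDM with NaN entries would silently poison
  every downstream correlation). Constant lower triangles are an error
  in `correlateRDMs`. Empty suprathreshold sets yield an empty
  `ClusterResult`, not an error. Searchlight centers with fewer than
  two in-mask voxels are skipped and reported.
- **Cluster statistic** is cluster size (count), not mass; the forming
  threshold is the per-point (1 − formingP) quantile of the
  permutation distribution, so it adapts to each point's null scale.
- **Units.** Time is always ms relative to stimulus onset, accuracies
  percent, dissimilarities unitless in [0, 2], voxel coordinates
  0-based integers.

## Verification strategy and problem sizes

The test suite checks each operation against an independent route:
RDMs against an elementwise correlation loop; decoding against
hand-enumerated folds classified by a second SVM implementation
(kernlab) on a toy where one planted outlier keeps the accuracy
informative; the sign-permutation test against exhaustive enumeration
of all 2^5 sign patterns; the searchlight sphere against a brute-force
lattice count (257 voxels at radius 4); the GLM against noise-free
recovery of planted HRF indices and betas.

Calibration suites run at sizes chosen to keep the full suite in the
minutes range while leaving the statistical regime intact: chance
decoding on label-permuted epochs (8 categories, 16 channels, 51 time
points, two assignment repetitions) is checked against a binomial 99%
band whose trial count deliberately excludes the time dimension —
time points reuse the same trials, so counting them would make the
band anti-conservatively narrow. Type-I error of the exhaustive
sign-permutation test is measured over 10,000 null simulations at
α = 0.001; cluster-correction FWER over 500 null simulations with 200
permutations each, with the forming threshold at p = 0.1 over 60
points because at stricter forming thresholds the max-cluster-size
null collapses onto a few small integers and the strict size
criterion becomes visibly conservative rather than miscalibrated;
bootstrap CIs are checked for ~95% coverage over 200 simulations with
between-subject latency jitter large enough (SD 30 ms) that the
bootstrap peak distribution spans several grid steps, which is the
regime where a normal-approximation CI is appropriate.

The trial-sequence generator exposes both catch-trial
parameterizations found in such designs — a spacing rule (one catch
after every 4–6 images) and a target proportion (20%) — as independent
modes, because the two constraints are not mutually consistent and the
package does not attempt to reconcile them.

## Known limitations

- Searchlight decoding loops over sphere centers in R; on
  whole-brain-sized grids this is slow. The structure (an accuracy
  engine applied per neighborhood) is the extension point for a
  compiled or parallel backend.
- The bootstrap CI is symmetric by construction (mean ± 1.96 SD); for
  strongly skewed peak distributions a percentile CI would differ, and
  `PeakCI` keeps the bootstrap samples so users can compute one.
- The searchlight fusion variant (RDMs per sphere rather than per ROI)
  is expressible through the exported pieces but has no convenience
  wrapper; ROI fusion is the supported surface.
- Statistical calibration is verified under exchangeable Gaussian
  noise; heavy-tailed or temporally autocorrelated noise is not part
  of the suite.
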