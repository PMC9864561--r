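# Pipeline configuration and orchestration. Conventions enforced
# throughout: time in ms relative to stimulus onset, accuracies in
# percent, voxel coordinates 0-based.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = "mvpafusion-results",
    n_categories = 8L,
    n_features = 30L,
    shared_fraction = 0.5,
    n_trials_per_cell = 8L,
    n_channels = 32L,
    noise_sd = 1.5,
    time_min_ms = -100,
    time_max_ms = 400,
    srate_hz = 100,
    group_size = 2L,
    n_repetitions = 5L,
    n_runs = 4L,
    n_voxels = 40L,
    radius_voxels = 4,
    fwhm_mm = 5,
    n_perm = 10000L,
    forming_p = 0.001,
    alpha = 0.05,
    n_boot = 1000L
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the stage parameters (defaults mirror the study's
#' analysis settings: 10,000 permutations, forming p 0.001, cluster
#' alpha 0.05, supertrials of 2 with 5 repetitions, searchlight radius
#' 4 voxels, 5 mm FWHM). Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param config named list (missing entries filled from defaults).
#' @return \code{readPipelineConfig} returns the completed config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  out
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config = list(), path) {
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  yaml::write_yaml(utils::modifyList(defaults, config), path)
  invisible(path)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates the analysis in study order on simulated data: generate
#' ground truth and epochs for all depiction types, decode time-resolved
#' category information per depiction, cross-decode between depiction
#' pairs, compute the temporal generalization matrix, run ROI decoding
#' and MEG-fMRI fusion on simulated betas, and test the group decoding
#' effect with a sign-permutation + cluster correction on
#' subject-resampled time courses. All outputs are CSV plus a JSON
#' provenance sidecar (stage parameters, seed, package version); the
#' run is deterministic given (config, seed).
#'
#' @param config named list as from \code{\link{readPipelineConfig}}
#'   (missing entries filled from defaults).
#' @return (invisibly) a list of result objects and output paths.
#' @export
runPipeline <- function(config = list()) {
  cfg <- utils::modifyList(pipelineDefaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- deriveSeeds(cfg$seed, 10)
  times <- seq(cfg$time_min_ms, cfg$time_max_ms,
               by = 1000 / cfg$srate_hz)
  gt <- makeGroundTruth(cfg$n_categories, cfg$n_features,
                        cfg$shared_fraction, noiseSd = cfg$noise_sd,
                        responseProfile = defaultResponseProfile(times),
                        seed = seeds[1])
  epochs <- simulateEpochs(gt, cfg$n_trials_per_cell, cfg$n_channels,
                           times = times, seed = seeds[2])
  results <- list(config = cfg)
  paths <- character()

  # time-resolved decoding per depiction
  sts <- list()
  for (d in DEPICTION_LEVELS) {
    ep_d <- subsetEpochs(epochs, depiction = d)
    sts[[d]] <- makeSupertrials(ep_d, cfg$group_size,
                                cfg$n_repetitions, seed = seeds[3])
    tc <- pairwiseDecodeTimecourse(sts[[d]])
    p <- file.path(cfg$out_dir, paste0("decoding_", d, ".csv"))
    writeTimeCourse(tc, p); paths <- c(paths, p)
    results[[paste0("decode_", d)]] <- tc
  }

  # cross-decoding photo vs drawing
  xtc <- crossDecode(sts$photo, sts$drawing, mode = "timecourse")
  p <- file.path(cfg$out_dir, "crossdecoding_photo_drawing.csv")
  writeTimeCourse(xtc, p); paths <- c(paths, p)
  results$cross_photo_drawing <- xtc

  # temporal generalization (first repetition only, photographs)
  tgm <- temporalGeneralization(sts$photo[1])
  p <- file.path(cfg$out_dir, "tgm_photo.csv")
  writeTGM(tgm, p); paths <- c(paths, p)
  results$tgm_photo <- tgm

  # fMRI side: ROI decoding and fusion
  betas <- simulateBetas(gt, cfg$n_runs, cfg$n_voxels,
                         noiseSd = cfg$noise_sd, seed = seeds[4])
  results$roi_accuracy <- pairwiseDecodeROI(betas)
  meg_rdms <- megRDMSeries(subsetEpochs(epochs, depiction = "photo"))
  fus <- fusionTimecourse(meg_rdms, betaRDM(betas), roi = "sim-roi")
  p <- file.path(cfg$out_dir, "fusion_sim-roi.csv")
  writeTimeCourse(fus, p); paths <- c(paths, p)
  results$fusion <- fus

  # group inference on per-"subject" decoding effects (subjects are
  # fresh simulated datasets at reduced size)
  tc_mat <- t(vapply(seq_len(5), function(s) {
    gt_s <- makeGroundTruth(cfg$n_categories, cfg$n_features,
                            cfg$shared_fraction,
                            noiseSd = cfg$noise_sd,
                            responseProfile =
                              defaultResponseProfile(times),
                            seed = seeds[5] + s)
    ep <- subsetEpochs(
      simulateEpochs(gt_s, 6, cfg$n_channels, times = times,
                     depictions = "photo", seed = seeds[6] + s),
      depiction = "photo")
    st <- makeSupertrials(ep, cfg$group_size, 1, seed = seeds[7] + s)
    pairwiseDecodeTimecourse(st)@values
  }, numeric(length(times))))
  cl <- clusterPermutation(tc_mat - 50, adjacency = "time",
                           formingP = cfg$forming_p,
                           alpha = cfg$alpha,
                           nPerm = min(cfg$n_perm, 2000L),
                           seed = seeds[8])
  results$cluster <- cl
  p <- file.path(cfg$out_dir, "cluster_significant_times.csv")
  sig_idx <- unlist(cl@clusters[cl@significant])
  utils::write.csv(data.frame(time_ms = times[sig_idx]), p,
                   row.names = FALSE)
  paths <- c(paths, p)

  meta <- list(package = "mvpafusion",
               version = as.character(utils::packageVersion("mvpafusion")),
               seed = cfg$seed, parameters = cfg,
               outputs = paths)
  mp <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE)
  results$paths <- c(paths, mp)
  invisible(results)
}
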