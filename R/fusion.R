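#' Time-resolved RDMs from an EpochSet
#'
#' For every time point, condition patterns are the trial-averaged
#' channel vectors per category, and the RDM is their pairwise
#' 1 - Pearson dissimilarity.
#'
#' @param epochs an \linkS4class{EpochSet} holding a single depiction
#'   type, with at least 2 trials per condition.
#' @return list with elements \code{rdms} (list of \linkS4class{RDM},
#'   one per time point) and \code{times}.
#' @export
megRDMSeries <- function(epochs) {
  if (length(unique(epochs@depiction)) > 1)
    stopf("epochs hold multiple depictions; subsetEpochs() first")
  cats <- sort(unique(epochs@category))
  n_t <- length(epochs@times)
  rdms <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    pat <- t(vapply(cats, function(cc)
      colMeans(matrix(epochs@data[epochs@category == cc, , t],
                      ncol = dim(epochs@data)[2])),
      numeric(dim(epochs@data)[2])))
    rownames(pat) <- as.character(cats)
    rdms[[t]] <- computeRDM(pat)
  }
  list(rdms = rdms, times = epochs@times)
}

#' MEG-fMRI fusion time course
#'
#' Correlates the lower-triangular part of each time-resolved MEG RDM
#' with the lower triangle of an ROI's fMRI RDM (Pearson), yielding one
#' correlation per time point: when the ROI's representational geometry
#' emerges in the MEG signal, the fusion curve peaks.
#'
#' @param megRdms output of \code{\link{megRDMSeries}}.
#' @param fmriRdm an \linkS4class{RDM} for one ROI (same conditions).
#' @param roi label carried into the result.
#' @return a \linkS4class{FusionTimeCourse}.
#' @export
fusionTimecourse <- function(megRdms, fmriRdm, roi = "roi") {
  if (!identical(megRdms$rdms[[1]]@conditionIds, fmriRdm@conditionIds))
    stopf("condition mismatch between MEG RDMs and fMRI RDM")
  vals <- vapply(megRdms$rdms, correlateRDMs, numeric(1), b = fmriRdm)
  new("FusionTimeCourse", values = vals, times = megRdms$times,
      roi = roi)
}

#' fMRI RDM from a BetaSet
#'
#' Averages run-wise patterns per condition, then computes the
#' 1 - Pearson RDM.
#'
#' @param betas a \linkS4class{BetaSet}.
#' @return an \linkS4class{RDM}.
#' @export
betaRDM <- function(betas) {
  mu <- apply(betas@betas, c(2, 3), mean)
  rownames(mu) <- as.character(seq_len(nrow(mu)))
  computeRDM(mu)
}
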