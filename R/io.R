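# On-disk containers. Epochs and gaze round-trip through a versioned
# R-native container (RDS of a validated named list); volumetric data
# through NIfTI; tabular results through CSV with an ms time header.

EPOCH_SCHEMA <- c("data", "category", "depiction", "times", "srate")

#' Write / read an EpochSet container
#'
#' Lossless round-trip: arrays are bit-exact and all metadata preserved.
#' Missing fields on read are reported by name.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{readEpochs} returns an \linkS4class{EpochSet};
#'   \code{writeEpochs} returns \code{path} invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  saveRDS(list(format = "mvpafusion-epochs-v1",
               data = epochs@data, category = epochs@category,
               depiction = epochs@depiction, times = epochs@times,
               srate = epochs@srate), path)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  obj <- readRDS(path)
  missing <- setdiff(EPOCH_SCHEMA, names(obj))
  if (length(missing))
    stopf("epoch container is missing field(s): %s",
          paste(missing, collapse = ", "))
  step <- 1000 / obj$srate
  if (length(obj$times) > 1 &&
      max(abs(diff(obj$times) - step)) > 1e-6)
    stopf("srate (%g Hz) does not match the time grid spacing",
          obj$srate)
  EpochSet(obj$data, obj$category, obj$depiction, obj$times,
           obj$srate)
}

#' Write / read a gaze epoch as a plain columnar file
#'
#' Tab-separated columns \code{time_s}, \code{x_deg}, \code{y_deg}.
#'
#' @param gaze a \linkS4class{GazeEpoch}.
#' @param path file path.
#' @param srate sampling rate in Hz (read side).
#' @return \code{readGaze} returns a \linkS4class{GazeEpoch}.
#' @export
writeGaze <- function(gaze, path) {
  n <- length(gaze@x)
  utils::write.table(
    data.frame(time_s = (seq_len(n) - 1) / gaze@srate,
               x_deg = gaze@x, y_deg = gaze@y),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGaze
#' @export
readGaze <- function(path, srate = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time_s", "x_deg", "y_deg")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopf("gaze file is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (is.null(srate))
    srate <- 1 / stats::median(diff(d$time_s))
  GazeEpoch(d$x_deg, d$y_deg, srate)
}

#' Write / read a volumetric map as NIfTI
#'
#' Axis order is x, y, z with 0-based voxel coordinates; NA outside the
#' mask becomes 0 with a companion mask volume when \code{maskPath} is
#' given.
#'
#' @param map an \linkS4class{AccuracyMap} or a numeric 3-D array.
#' @param path NIfTI file path (.nii / .nii.gz).
#' @param maskPath optional path for the binary mask volume.
#' @param voxelSizeMm isotropic voxel size stored in the header.
#' @return \code{readVolume} returns a list with \code{values} (3-D
#'   array, NA outside the mask when a mask is supplied) and
#'   \code{mask}.
#' @export
writeVolume <- function(map, path, maskPath = NULL,
                        voxelSizeMm = 2.5) {
  if (is(map, "AccuracyMap")) {
    vals <- map@values; mask <- map@mask
  } else {
    vals <- map; mask <- !is.na(vals)
  }
  out <- vals
  out[is.na(out)] <- 0
  img <- RNifti::asNifti(out, reference = NULL)
  RNifti::pixdim(img) <- rep(voxelSizeMm, 3)
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask),
                                             dim(mask))), maskPath)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, maskPath = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  mask <- if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    if (!identical(dim(m), dim(img)))
      stopf("mask dimensions (%s) do not match the volume (%s)",
            paste(dim(m), collapse = "x"),
            paste(dim(img), collapse = "x"))
    array(as.numeric(m) > 0.5, dim(m))
  } else array(TRUE, dim(img))
  vals[!mask] <- NA_real_
  list(values = vals, mask = mask)
}

#' Write / read a time course as CSV with an ms time header
#'
#' @param tc a \linkS4class{TimeCourse} or
#'   \linkS4class{FusionTimeCourse}.
#' @param path CSV path.
#' @return \code{readTimeCourse} returns a data.frame with columns
#'   \code{time_ms} and \code{value}.
#' @export
writeTimeCourse <- function(tc, path) {
  utils::write.csv(data.frame(time_ms = tc@times, value = tc@values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeCourse
#' @export
readTimeCourse <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(d)))
    stopf("time-course file is missing time_ms / value columns")
  d
}

#' Write a temporal generalization matrix as CSV
#'
#' Rows are training times, columns test times (ms header).
#'
#' @param tgm a \linkS4class{TGMatrix}.
#' @param path CSV path.
#' @export
writeTGM <- function(tgm, path) {
  m <- tgm@values
  dimnames(m) <- list(train_ms = tgm@times, test_ms = tgm@times)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
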