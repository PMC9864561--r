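#' Compute a representational dissimilarity matrix
#'
#' Pairwise dissimilarities between condition pattern vectors, defined as
#' 1 - Pearson correlation (range [0, 2]). If run- or trial-wise patterns
#' exist per condition, average them first (see
#' \code{\link{megRDMSeries}} for the MEG case); this function expects one
#' pattern per condition.
#'
#' @param patterns conditions x features numeric matrix; row names become
#'   condition ids.
#' @return an \linkS4class{RDM}.
#' @examples
#' p <- matrix(rnorm(40), 4, dimnames = list(letters[1:4], NULL))
#' computeRDM(p)
#' @export
computeRDM <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2)
    stopf("at least 2 features are required to correlate patterns")
  ids <- rownames(patterns) %||% as.character(seq_len(nrow(patterns)))
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0))
    stopf("degenerate input: condition(s) %s have zero-variance patterns",
          paste(ids[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(patterns))
  d[abs(d) < 1e-15] <- 0   # clamp correlation round-off on the diagonal
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(ids, ids)
  new("RDM", values = d, conditionIds = ids)
}

#' Extract the lower triangle of an RDM
#'
#' Strictly below-diagonal entries in fixed row-major order, i.e. pairs
#' (2,1), (3,1), (3,2), (4,1), ... — length n(n-1)/2. Fusion and RDM
#' comparisons depend only on this ordering being used consistently.
#'
#' @param rdm an \linkS4class{RDM} or square numeric matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
lowerTriangle <- function(rdm) {
  v <- if (is(rdm, "RDM")) rdm@values else as.matrix(rdm)
  idx <- which(row(v) > col(v))
  idx <- idx[order(row(v)[idx], col(v)[idx])]
  v[idx]
}

#' Rebuild a symmetric RDM from its lower triangle
#'
#' Inverse of \code{\link{lowerTriangle}} (row-major ordering).
#'
#' @param lt numeric vector of length n(n-1)/2.
#' @param conditionIds optional labels.
#' @return an \linkS4class{RDM} with zero diagonal.
#' @export
symmetrizeRDM <- function(lt, conditionIds = NULL) {
  n <- (1 + sqrt(1 + 8 * length(lt))) / 2
  if (n != round(n))
    stopf("length %d is not n(n-1)/2 for integer n", length(lt))
  v <- matrix(0, n, n)
  k <- 1
  for (i in 2:n) for (j in 1:(i - 1)) {
    v[i, j] <- v[j, i] <- lt[k]; k <- k + 1
  }
  ids <- conditionIds %||% as.character(seq_len(n))
  dimnames(v) <- list(ids, ids)
  new("RDM", values = v, conditionIds = ids)
}

#' Correlate two RDMs
#'
#' Pearson correlation (default; Spearman available for robustness
#' checks) of the lower-triangular parts of two RDMs over the same
#' conditions.
#'
#' @param a,b \linkS4class{RDM} objects with matching condition sets.
#' @param method "pearson" or "spearman".
#' @return a single correlation value.
#' @export
correlateRDMs <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dim(a@values), dim(b@values)))
    stopf("RDMs must have the same size")
  if (!identical(a@conditionIds, b@conditionIds))
    stopf("RDMs must share the same condition ordering")
  la <- lowerTriangle(a); lb <- lowerTriangle(b)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stopf("degenerate input: constant lower triangle")
  stats::cor(la, lb, method = method)
}

#' Read and write RDMs as labeled CSV matrices
#'
#' @param rdm an \linkS4class{RDM}.
#' @param path file path.
#' @return \code{readRDM} returns an \linkS4class{RDM};
#'   \code{writeRDM} returns \code{path} invisibly.
#' @export
writeRDM <- function(rdm, path) {
  utils::write.csv(as.data.frame(rdm@values), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeRDM
#' @export
readRDM <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  v <- as.matrix(d)
  new("RDM", values = v, conditionIds = rownames(v))
}
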