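# Internal helpers: argument checking and seeded RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
}

assertCount <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
}

assertNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name,
          format(min), format(max))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic functions route their
# randomness through this, so results are reproducible given (params, seed)
# and do not perturb the user's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    assertCount(seed, "seed", min = 0)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream of sub-seeds from a master seed; keeps every derived
# seed a valid 32-bit integer.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Downsample a uniform time grid by an integer factor
#'
#' Keeps every \code{factor}-th sample starting at the first, mirroring
#' decimation of a 1000 Hz epoch grid to 100 Hz.
#'
#' @param times numeric, uniformly spaced sample times.
#' @param factor integer decimation factor.
#' @return the retained sample times.
#' @examples
#' length(downsampleTimes(seq(-100, 1001), 10))  # 111
#' @export
downsampleTimes <- function(times, factor) {
  assertCount(factor, "factor", min = 1)
  times[seq(1, length(times), by = factor)]
}
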