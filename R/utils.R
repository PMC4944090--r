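# Internal helpers shared across modules.

#' @importFrom stats runif rnorm kmeans cor complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Absolute circular difference between two headings in degrees, in [0, 180].
circularDiffDeg <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n child seeds from a parent seed, each below 2^31.
deriveSeeds <- function(seed, n) {
  withLocalSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Min-max scale a numeric vector to [0, 1]; zero range maps to 0.
minMaxScale <- function(x, lo = min(x, na.rm = TRUE), hi = max(x, na.rm = TRUE)) {
  if (!is.finite(lo) || !is.finite(hi)) stop("cannot scale a feature with no finite values")
  if (hi == lo) return(ifelse(is.na(x), NA_real_, 0))
  (x - lo) / (hi - lo)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
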