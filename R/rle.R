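# Run-length encoding of symbol strings and the RLE matrix variants.

#' Run-length encode a symbol string
#'
#' Compresses a symbol sequence into its ordered maximal runs: the string
#' `22122221222` becomes the pairs (2,2) (1,1) (2,4) (1,1) (2,3). The
#' encoding is lossless; [runLengthDecode()] inverts it exactly.
#'
#' @param s a [SymbolString-class] or a plain integer vector.
#' @return a `data.frame` with columns `symbol` and `runLength`, one row
#'   per maximal run, in order of occurrence.
#' @examples
#' runLengthEncode(c(2L, 2L, 1L, 2L, 2L, 2L, 2L))
#' @export
runLengthEncode <- function(s) {
  v <- if (is(s, "SymbolString")) s@symbols else as.integer(s)
  if (!length(v)) return(data.frame(symbol = integer(), runLength = integer()))
  r <- rle(v)
  data.frame(symbol = r$values, runLength = r$lengths)
}

#' Decode a run-length sequence
#'
#' @param runs a `data.frame` with columns `symbol` and `runLength`, as
#'   produced by [runLengthEncode()].
#' @return the integer symbol vector.
#' @examples
#' runLengthDecode(data.frame(symbol = c(2, 1, 2), runLength = c(2, 1, 4)))
#' @export
runLengthDecode <- function(runs) {
  stopIfNot(all(c("symbol", "runLength") %in% names(runs)),
            "runs must have columns symbol and runLength")
  if (!nrow(runs)) return(integer())
  if (any(runs$runLength < 1)) stop("run lengths must be >= 1", call. = FALSE)
  inverse.rle(structure(list(lengths = as.integer(runs$runLength),
                             values = as.integer(runs$symbol)), class = "rle"))
}

#' Build the run-length bin scheme
#'
#' Discretizes run lengths into the bins {1}, {2}, {3}, then dyadic spans
#' [4,8], [9,16], [17,32], [33,64], ... doubling until `maxRun` is covered,
#' with the final bin truncated at `maxRun`. For a maximum run length of 37
#' this gives the 7 bins {1} {2} {3} {4-8} {9-16} {17-32} {33-37}. Binning
#' reduces the sparsity of the run-length matrices, since long runs are rare.
#'
#' @param maxRun the maximum run length to cover (>= 1).
#' @return a [BinScheme-class].
#' @examples
#' makeBinScheme(37)
#' @export
makeBinScheme <- function(maxRun) {
  maxRun <- as.integer(maxRun)
  stopIfNot(length(maxRun) == 1L && !is.na(maxRun) && maxRun >= 1L,
            "maxRun must be a single integer >= 1")
  lower <- integer(); upper <- integer()
  lo <- 1L
  nextPow <- 8L  # after the singleton bins {1},{2},{3}: [4,8],[9,16],[17,32],...
  while (lo <= maxRun) {
    if (lo <= 3L) {
      hi <- lo
    } else {
      hi <- min(maxRun, nextPow)
      nextPow <- nextPow * 2L
    }
    lower <- c(lower, lo); upper <- c(upper, hi)
    lo <- hi + 1L
  }
  new("BinScheme", lower = lower, upper = upper, maxRun = maxRun)
}

# Bin index of each run length under a scheme.
.binIndex <- function(lengths, bins) {
  findInterval(lengths, c(bins@lower, bins@maxRun + 1L),
               rightmost.closed = FALSE)
}

#' Build a run-length encoding matrix
#'
#' Counts the maximal runs of one animal into the grid P(i, j): rows are
#' symbols 1..`nSymbols`, columns (possibly binned) run lengths. The
#' variants differ in the column range and column values:
#' \describe{
#'   \item{IMF}{columns 1..(this animal's maximum run length).}
#'   \item{AMF}{columns 1..`globalMaxRun` (maximum across all animals), so
#'     matrices are comparable across animals of different track lengths.}
#'   \item{BAMF}{run lengths aggregated into `bins`; the column value used
#'     in descriptor formulas is the bin index.}
#'   \item{BAAMF}{same counts as BAMF, but each column value is this
#'     animal's mean observed run length within the bin; bins with no runs
#'     fall back to the bin midpoint and are flagged in `emptyBins`.}
#' }
#' Totals `nRuns` (number of runs, n_r) and `nSteps` (number of symbols,
#' n_p) are recorded for the descriptor formulas.
#'
#' @param runs a `data.frame` from [runLengthEncode()], or a
#'   [SymbolString-class] (encoded internally).
#' @param kind `"IMF"`, `"AMF"`, `"BAMF"` or `"BAAMF"` (log variants are
#'   produced by [logTransform()]).
#' @param nSymbols alphabet size M (rows).
#' @param globalMaxRun maximum run length across all animals; required for
#'   AMF/BAMF/BAAMF.
#' @param bins a [BinScheme-class] for the binned kinds; defaults to
#'   `makeBinScheme(globalMaxRun)`.
#' @param animalId,group identity attached to the output (taken from `runs`
#'   when it is a [SymbolString-class]).
#' @return a [RLEMatrix-class].
#' @examples
#' rl <- runLengthEncode(c(2,2,1,2,2,2,2,1,2,2,2))
#' buildRLEMatrix(rl, "IMF", nSymbols = 2)
#' @export
buildRLEMatrix <- function(runs, kind = c("IMF", "AMF", "BAMF", "BAAMF"),
                           nSymbols = 2L, globalMaxRun = NULL, bins = NULL,
                           animalId = "animal", group = "NA") {
  kind <- match.arg(kind)
  if (is(runs, "SymbolString")) {
    animalId <- runs@animalId
    group <- runs@group
    nSymbols <- max(nSymbols, runs@k)
    runs <- runLengthEncode(runs)
  }
  nSymbols <- as.integer(nSymbols)
  nr <- nrow(runs)
  np <- if (nr) sum(runs$runLength) else 0L
  if (nr && any(runs$symbol > nSymbols))
    stop("runs contain symbols beyond nSymbols", call. = FALSE)

  binScheme <- NULL
  emptyBins <- logical()
  if (kind == "IMF") {
    p <- if (nr) max(runs$runLength) else 0L
    cols <- seq_len(p)
    colIdx <- runs$runLength
    colVal <- as.numeric(cols)
  } else {
    stopIfNot(!is.null(globalMaxRun) && globalMaxRun >= 1,
              sprintf("%s requires globalMaxRun", kind))
    globalMaxRun <- as.integer(globalMaxRun)
    if (nr && max(runs$runLength) > globalMaxRun)
      stop(sprintf("run of length %d exceeds globalMaxRun = %d",
                   max(runs$runLength), globalMaxRun), call. = FALSE)
    if (kind == "AMF") {
      cols <- seq_len(globalMaxRun)
      colIdx <- runs$runLength
      colVal <- as.numeric(cols)
    } else {
      if (is.null(bins)) bins <- makeBinScheme(globalMaxRun)
      stopIfNot(is(bins, "BinScheme"), "bins must be a BinScheme")
      stopIfNot(bins@maxRun >= globalMaxRun, "bin scheme does not cover globalMaxRun")
      binScheme <- bins
      cols <- seq_along(bins@lower)
      colIdx <- if (nr) .binIndex(runs$runLength, bins) else integer()
      if (kind == "BAMF") {
        colVal <- as.numeric(cols)
      } else {  # BAAMF: per-bin mean observed run length, midpoint if empty
        colVal <- (bins@lower + bins@upper) / 2
        emptyBins <- rep(TRUE, length(cols))
        if (nr) {
          for (b in cols) {
            lens <- runs$runLength[colIdx == b]
            # a run falling in the bin contributes once per run occurrence
            if (length(lens)) {
              colVal[b] <- mean(lens)
              emptyBins[b] <- FALSE
            }
          }
        }
      }
    }
  }
  P <- matrix(0, nrow = nSymbols, ncol = length(cols),
              dimnames = list(paste0("sym", seq_len(nSymbols)), NULL))
  if (nr) for (r in seq_len(nr))
    P[runs$symbol[r], colIdx[r]] <- P[runs$symbol[r], colIdx[r]] + 1
  new("RLEMatrix", animalId = animalId, group = group, kind = kind,
      counts = P, colValues = colVal, nRuns = as.numeric(nr),
      nSteps = as.numeric(np), binScheme = binScheme, emptyBins = emptyBins)
}

#' Log-transform an IMF or AMF matrix
#'
#' Applies ln(1 + count) entrywise, producing the IMFL/AMFL variants. The
#' +1 offset keeps the pervasive zero entries at zero. `nRuns` and `nSteps`
#' are carried over unchanged so RP keeps its meaning.
#'
#' @param m a [RLEMatrix-class] of kind IMF or AMF.
#' @return a [RLEMatrix-class] of kind IMFL or AMFL.
#' @examples
#' rl <- runLengthEncode(c(1,1,1,2,2))
#' logTransform(buildRLEMatrix(rl, "IMF", nSymbols = 2))
#' @export
logTransform <- function(m) {
  stopIfNot(is(m, "RLEMatrix"), "m must be an RLEMatrix")
  if (!m@kind %in% c("IMF", "AMF"))
    stop(sprintf("log transform is defined for IMF/AMF, not %s", m@kind),
         call. = FALSE)
  m@counts <- log1p(m@counts)
  m@kind <- paste0(m@kind, "L")
  m
}

#' Build matrices of one kind for a whole cohort
#'
#' Encodes every symbol string and builds one [RLEMatrix-class] per animal,
#' sharing the cohort-wide maximum run length (and bin scheme) across
#' animals for the kinds that need it. `"IMFL"`/`"AMFL"` are built as
#' IMF/AMF followed by [logTransform()].
#'
#' @param strings a list of [SymbolString-class] objects.
#' @param kind one of `"IMF"`, `"AMF"`, `"BAMF"`, `"BAAMF"`, `"IMFL"`, `"AMFL"`.
#' @return a list of [RLEMatrix-class] objects, one per string.
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(3, 40, seed = 2))
#' mod <- fitStepClusters(tabs, seed = 1)
#' mats <- buildCohortMatrices(symbolize(tabs, mod), "BAMF")
#' mats[[1]]
#' @export
buildCohortMatrices <- function(strings, kind = .rleKinds) {
  kind <- match.arg(kind)
  base <- sub("L$", "", kind)
  runsList <- lapply(strings, runLengthEncode)
  maxRuns <- vapply(runsList, function(r) if (nrow(r)) max(r$runLength) else 0L, 1L)
  gmax <- max(maxRuns, 1L)
  bins <- if (base %in% c("BAMF", "BAAMF")) makeBinScheme(gmax) else NULL
  k <- max(vapply(strings, function(s) s@k, 1L))
  out <- lapply(seq_along(strings), function(i) {
    m <- buildRLEMatrix(runsList[[i]], base, nSymbols = k,
                        globalMaxRun = if (base == "IMF") NULL else gmax,
                        bins = bins, animalId = strings[[i]]@animalId,
                        group = strings[[i]]@group)
    if (kind %in% c("IMFL", "AMFL")) m <- logTransform(m) else m
    m
  })
  names(out) <- vapply(strings, function(s) s@animalId, "")
  out
}
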