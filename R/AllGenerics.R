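#' @import methods
NULL

#' Accessors for wormpath objects
#'
#' `animalId()` and `groupLabel()` return the animal identifier and the
#' experimental group label attached to a per-animal object (trajectory,
#' step table, symbol string or run-length matrix). `samples()` returns the
#' raw timestamped centroid samples of a [WormTrajectory-class], `steps()`
#' the per-step feature table of a [StepTable-class], and `symbols()` the
#' integer symbol sequence of a [SymbolString-class].
#'
#' @param x a wormpath object.
#' @return `animalId`/`groupLabel`: a character scalar; `samples`/`steps`:
#'   a `data.frame`; `symbols`: an integer vector.
#' @name accessors
#' @aliases animalId groupLabel samples steps symbols
#' @examples
#' tr <- simulateWormPath(simParams(durationS = 10, seed = 1))
#' animalId(tr)
#' head(samples(tr))
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("steps", function(x) standardGeneric("steps"))

#' @rdname accessors
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))

#' Run-length matrix accessors
#'
#' `rleCounts()` returns the count grid P(i, j) of a [RLEMatrix-class]
#' (transformed values for the log variants), `colValues()` the run-length
#' value associated with each column (used as j in the descriptor formulas),
#' `nRuns()` the total number of runs n_r, and `nSteps()` the total number
#' of symbols n_p in the source string.
#'
#' @param x a [RLEMatrix-class].
#' @return `rleCounts`: a numeric matrix; `colValues`: a numeric vector;
#'   `nRuns`/`nSteps`: a single number.
#' @name rle-accessors
#' @aliases rleCounts colValues nRuns nSteps
#' @export
setGeneric("rleCounts", function(x) standardGeneric("rleCounts"))

#' @rdname rle-accessors
#' @export
setGeneric("colValues", function(x) standardGeneric("colValues"))

#' @rdname rle-accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname rle-accessors
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))
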