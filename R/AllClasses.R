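#' Simulation parameters for the synthetic path generator
#'
#' Parameter container for [simulateWormPath()]. The simulator is a
#' discrete-time two-regime (roam/turn) process: regime switches and heading
#' updates happen on a 1-second clock, matching the 1-second resampling grid
#' used downstream, while the centroid advances frame by frame at
#' `frameRateHz` along the current heading.
#'
#' @slot durationS track duration in seconds.
#' @slot frameRateHz samples per second (default 30).
#' @slot speedMeanMmS,speedSdMmS per-frame crawling speed distribution
#'   (mm/s), Gaussian truncated at zero.
#' @slot pRoamToTurn,pTurnToRoam per-second regime switch probabilities.
#' @slot roamHeadingSdDeg per-second Gaussian heading jitter while roaming
#'   (degrees).
#' @slot turnAngleMinDeg,turnAngleMaxDeg magnitude range of the uniform
#'   reorientation drawn each second in the turn regime (degrees).
#' @slot seed integer RNG seed.
#' @seealso [simParams()], [sharpTurnParams()], [shallowTurnParams()]
#' @export
setClass("SimParams",
  representation(
    durationS = "numeric", frameRateHz = "numeric",
    speedMeanMmS = "numeric", speedSdMmS = "numeric",
    pRoamToTurn = "numeric", pTurnToRoam = "numeric",
    roamHeadingSdDeg = "numeric",
    turnAngleMinDeg = "numeric", turnAngleMaxDeg = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@durationS > 0, "durationS must be > 0")
  chk(object@frameRateHz > 0, "frameRateHz must be > 0")
  chk(object@speedSdMmS >= 0, "speedSdMmS must be >= 0")
  chk(object@speedMeanMmS >= 0, "speedMeanMmS must be >= 0")
  chk(object@pRoamToTurn >= 0 && object@pRoamToTurn <= 1,
      "pRoamToTurn must be in [0, 1]")
  chk(object@pTurnToRoam >= 0 && object@pTurnToRoam <= 1,
      "pTurnToRoam must be in [0, 1]")
  chk(object@roamHeadingSdDeg >= 0, "roamHeadingSdDeg must be >= 0")
  chk(object@turnAngleMinDeg >= 0, "turnAngleMinDeg must be >= 0")
  chk(object@turnAngleMaxDeg <= 180, "turnAngleMaxDeg must be <= 180")
  chk(object@turnAngleMinDeg <= object@turnAngleMaxDeg,
      "turnAngleMinDeg must be <= turnAngleMaxDeg")
  if (length(msg)) msg else TRUE
})

#' A single-animal centroid trajectory
#'
#' Raw timestamped centroid track for one animal: one row per video frame,
#' with time in seconds and x/y centroid position in mm.
#'
#' @slot animalId animal identifier.
#' @slot group experimental group label (e.g. `"N2_f"`, `"tph-1_nf"`).
#' @slot samples `data.frame` with columns `t`, `x`, `y`; `t` strictly
#'   increasing, at least two rows, finite coordinates.
#' @seealso [simulateWormPath()], [resamplePath()], [readTrajectoryCSV()]
#' @export
setClass("WormTrajectory",
  representation(animalId = "character", group = "character",
                 samples = "data.frame")
)

setValidity("WormTrajectory", function(object) {
  s <- object@samples
  if (!all(c("t", "x", "y") %in% names(s)))
    return("samples must have columns t, x, y")
  if (nrow(s) < 2) return("trajectory needs at least 2 samples")
  if (!all(is.finite(s$t)) || !all(is.finite(s$x)) || !all(is.finite(s$y)))
    return("trajectory samples must be finite")
  if (any(diff(s$t) <= 0)) return("sample times must be strictly increasing")
  TRUE
})

#' A trajectory resampled on a regular time grid
#'
#' Centroid positions linearly interpolated onto a grid of spacing
#' `deltaTs` seconds, the first stage of step extraction.
#'
#' @slot animalId,group identity carried over from the trajectory.
#' @slot points `data.frame` with columns `t`, `x`, `y` at regular spacing.
#' @slot deltaTs grid interval in seconds (default 1).
#' @seealso [resamplePath()], [detectTurningEvents()]
#' @export
setClass("SampledPath",
  representation(animalId = "character", group = "character",
                 points = "data.frame", deltaTs = "numeric")
)

setValidity("SampledPath", function(object) {
  p <- object@points
  if (nrow(p) < 2) return("sampled path needs at least 2 points")
  dt <- diff(p$t)
  if (any(abs(dt - object@deltaTs) > 1e-8 * max(1, object@deltaTs)))
    return("points must be spaced deltaTs apart")
  TRUE
})

#' Turning events of a sampled path
#'
#' Ordered path points where the movement heading deviates from the
#' reference heading (established at the previous turning event) by more
#' than the threshold angle. The first sampled point is always the initial
#' turning event.
#'
#' @slot animalId,group identity carried over.
#' @slot events `data.frame` with columns `teIndex`, `t`, `x`, `y`.
#' @slot thetaDeg detection threshold in degrees (default 40).
#' @seealso [detectTurningEvents()], [computeSteps()]
#' @export
setClass("TurningEvents",
  representation(animalId = "character", group = "character",
                 events = "data.frame", thetaDeg = "numeric")
)

setValidity("TurningEvents", function(object) {
  e <- object@events
  if (nrow(e) >= 1 && e$teIndex[1] != 0L)
    return("first event must be the initial turning event (index 0)")
  if (nrow(e) >= 2 && any(diff(e$t) <= 0))
    return("event times must be strictly increasing")
  TRUE
})

#' Per-animal step table
#'
#' Ordered steps between consecutive turning events. Each step carries its
#' length (mm), traversal speed (mm/s) and the interior angle (degrees, in
#' [0, 180], 180 = straight continuation, 0 = full reversal) it forms with
#' the preceding step; the first step of a path has no angle (`NA`).
#' Normalized feature columns are filled by [normalizeFeatures()] using a
#' min-max scale pooled across all animals of a run.
#'
#' @slot animalId,group identity carried over.
#' @slot steps `data.frame` with columns `stepIdx`, `tStart`, `tEnd`,
#'   `lengthMm`, `angleDeg`, `speedMmS`, `lengthNorm`, `angleNorm`,
#'   `speedNorm`.
#' @slot normalized `TRUE` once pooled min-max normalization has been applied.
#' @slot degenerateFeatures names of features whose pooled range was zero
#'   (mapped to 0 everywhere).
#' @seealso [computeSteps()], [normalizeFeatures()], [fitStepClusters()]
#' @export
setClass("StepTable",
  representation(animalId = "character", group = "character",
                 steps = "data.frame", normalized = "logical",
                 degenerateFeatures = "character")
)

setValidity("StepTable", function(object) {
  s <- object@steps
  need <- c("stepIdx", "tStart", "tEnd", "lengthMm", "angleDeg", "speedMmS",
            "lengthNorm", "angleNorm", "speedNorm")
  if (!all(need %in% names(s))) return("steps is missing required columns")
  if (nrow(s)) {
    if (any(s$lengthMm < 0, na.rm = TRUE)) return("step lengths must be >= 0")
    if (any(s$speedMmS < 0, na.rm = TRUE)) return("step speeds must be >= 0")
    ang <- s$angleDeg[!is.na(s$angleDeg)]
    if (length(ang) && (any(ang < 0) || any(ang > 180)))
      return("angles must be in [0, 180]")
  }
  TRUE
})

#' Fitted step-symbolization model
#'
#' A k-means model over normalized step features (length, angle, speed),
#' with clusters relabeled to symbols 1..k by ascending mean raw angle so
#' that symbol 1 is always the sharpest-turn cluster (for k = 2: symbol 1 =
#' sharp turn, angle < ~90 degrees; symbol 2 = shallow turn).
#'
#' @slot k number of clusters, 2..5.
#' @slot centers k x 3 matrix of centroids in normalized feature space,
#'   rows ordered by symbol.
#' @slot clusterRanges `data.frame` of per-symbol min/max of the raw angle,
#'   length and speed of assigned steps.
#' @slot seed RNG seed used for fitting.
#' @seealso [fitStepClusters()], [symbolize()]
#' @export
setClass("StepClusterModel",
  representation(k = "integer", centers = "matrix",
                 clusterRanges = "data.frame", seed = "integer")
)

setValidity("StepClusterModel", function(object) {
  if (object@k < 2L || object@k > 5L) return("k must be in [2, 5]")
  if (nrow(object@centers) != object@k) return("centers must have k rows")
  if (!all(is.finite(object@centers))) return("centers must be finite")
  TRUE
})

#' Per-animal symbol string
#'
#' The ordered sequence of movement-pattern symbols for one animal, one
#' symbol per angle-bearing step. With k = 2, symbol 1 denotes a sharp turn
#' and symbol 2 a shallow turn.
#'
#' @slot animalId,group identity carried over.
#' @slot symbols integer vector over the alphabet 1..k.
#' @slot k alphabet size.
#' @seealso [symbolize()], [runLengthEncode()]
#' @export
setClass("SymbolString",
  representation(animalId = "character", group = "character",
                 symbols = "integer", k = "integer")
)

setValidity("SymbolString", function(object) {
  if (length(object@symbols) &&
      (any(object@symbols < 1L) || any(object@symbols > object@k)))
    return("symbols must lie in 1..k")
  TRUE
})

#' Run-length bin scheme
#'
#' Discretization of run lengths into bins {1}, {2}, {3}, then dyadic spans
#' [4,8], [9,16], [17,32], ... doubling until the maximum run length is
#' covered, with the last bin truncated at the maximum.
#'
#' @slot lower,upper integer bin edges (inclusive).
#' @slot maxRun the maximum run length the scheme covers.
#' @seealso [makeBinScheme()], [buildRLEMatrix()]
#' @export
setClass("BinScheme",
  representation(lower = "integer", upper = "integer", maxRun = "integer")
)

setValidity("BinScheme", function(object) {
  if (length(object@lower) != length(object@upper))
    return("lower and upper must have equal length")
  if (any(object@upper < object@lower)) return("bins must be non-empty")
  if (object@lower[1] != 1L || object@upper[length(object@upper)] != object@maxRun)
    return("bins must partition [1, maxRun]")
  if (length(object@lower) > 1 &&
      any(object@lower[-1] != object@upper[-length(object@upper)] + 1L))
    return("bins must be contiguous")
  TRUE
})

#' Run-length encoding matrix
#'
#' The count grid P(i, j): how many times symbol i occurs in a maximal run
#' of (possibly binned) length j. Variants: `IMF` (columns up to the
#' animal's own maximum run), `AMF` (up to the maximum across all animals),
#' `BAMF` (binned, column value = bin index), `BAAMF` (binned, column value
#' = this animal's mean observed run length within the bin), and `IMFL`/
#' `AMFL`, the ln(1 + count) transforms of IMF/AMF.
#'
#' @slot animalId,group identity carried over.
#' @slot kind one of `"IMF"`, `"AMF"`, `"BAMF"`, `"BAAMF"`, `"IMFL"`, `"AMFL"`.
#' @slot counts M x p numeric grid (counts, or transformed values for the
#'   log kinds).
#' @slot colValues per-column run-length value used as j in the descriptor
#'   formulas.
#' @slot nRuns total number of runs n_r in the source string.
#' @slot nSteps total number of symbols n_p in the source string.
#' @slot binScheme the [BinScheme-class] used (binned kinds) or `NULL`.
#' @slot emptyBins for BAAMF, logical flags marking bins with no observed
#'   runs, whose column value fell back to the bin midpoint.
#' @seealso [buildRLEMatrix()], [computeDescriptors()]
#' @export
setClass("RLEMatrix",
  representation(animalId = "character", group = "character",
                 kind = "character", counts = "matrix",
                 colValues = "numeric", nRuns = "numeric", nSteps = "numeric",
                 binScheme = "ANY", emptyBins = "logical")
)

.rleKinds <- c("IMF", "AMF", "BAMF", "BAAMF", "IMFL", "AMFL")

setValidity("RLEMatrix", function(object) {
  if (!object@kind %in% .rleKinds)
    return(sprintf("kind must be one of %s", paste(.rleKinds, collapse = ", ")))
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@colValues) != ncol(object@counts))
    return("colValues must have one value per column")
  if (object@nRuns < 0 || object@nSteps < 0) return("nRuns/nSteps must be >= 0")
  TRUE
})

#' Animal-level clustering by descriptor profiles
#'
#' Result of k-means over per-animal run-length descriptor vectors, plus
#' the per-(group, cluster) composition ratios: the share of each cluster
#' contributed by a group, and the share of each group falling in a cluster.
#'
#' @slot k number of clusters.
#' @slot assignment integer cluster id per animal, named by animal id.
#' @slot groups group label per animal, named by animal id.
#' @slot features descriptor names used.
#' @slot seed RNG seed used.
#' @seealso [clusterWorms()], [compositionTable()]
#' @export
setClass("WormClustering",
  representation(k = "integer", assignment = "integer", groups = "character",
                 features = "character", seed = "integer")
)

setValidity("WormClustering", function(object) {
  if (length(object@assignment) != length(object@groups))
    return("assignment and groups must cover the same animals")
  if (!identical(names(object@assignment), names(object@groups)))
    return("assignment and groups must be named by the same animal ids")
  if (length(object@assignment) &&
      (any(object@assignment < 1L) || any(object@assignment > object@k)))
    return("cluster ids must lie in 1..k")
  TRUE
})
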