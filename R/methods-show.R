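# Accessor methods and show() methods.

#' @rdname accessors
#' @export
setMethod("animalId", "WormTrajectory", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "SampledPath", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "TurningEvents", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "StepTable", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "SymbolString", function(x) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "RLEMatrix", function(x) x@animalId)

#' @rdname accessors
#' @export
setMethod("groupLabel", "WormTrajectory", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SampledPath", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("groupLabel", "TurningEvents", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("groupLabel", "StepTable", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SymbolString", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("groupLabel", "RLEMatrix", function(x) x@group)

#' @rdname accessors
#' @export
setMethod("samples", "WormTrajectory", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("steps", "StepTable", function(x) x@steps)

#' @rdname accessors
#' @export
setMethod("symbols", "SymbolString", function(x) x@symbols)

#' @rdname rle-accessors
#' @export
setMethod("rleCounts", "RLEMatrix", function(x) x@counts)
#' @rdname rle-accessors
#' @export
setMethod("colValues", "RLEMatrix", function(x) x@colValues)
#' @rdname rle-accessors
#' @export
setMethod("nRuns", "RLEMatrix", function(x) x@nRuns)
#' @rdname rle-accessors
#' @export
setMethod("nSteps", "RLEMatrix", function(x) x@nSteps)

setMethod("show", "WormTrajectory", function(object) {
  s <- object@samples
  cat(sprintf("WormTrajectory '%s' (group %s): %d samples, %.1f s\n",
              object@animalId, object@group, nrow(s),
              s$t[nrow(s)] - s$t[1]))
})

setMethod("show", "SampledPath", function(object) {
  cat(sprintf("SampledPath '%s': %d points at dt = %g s\n",
              object@animalId, nrow(object@points), object@deltaTs))
})

setMethod("show", "TurningEvents", function(object) {
  cat(sprintf("TurningEvents '%s': %d events (theta = %g deg)\n",
              object@animalId, nrow(object@events), object@thetaDeg))
})

setMethod("show", "StepTable", function(object) {
  cat(sprintf("StepTable '%s' (group %s): %d steps%s\n",
              object@animalId, object@group, nrow(object@steps),
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "StepClusterModel", function(object) {
  cat(sprintf("StepClusterModel: k = %d (symbols ordered by ascending mean angle)\n",
              object@k))
  print(object@clusterRanges)
})

setMethod("show", "SymbolString", function(object) {
  s <- paste(object@symbols, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 60), "...")
  cat(sprintf("SymbolString '%s' (group %s, k = %d, %d symbols): %s\n",
              object@animalId, object@group, object@k,
              length(object@symbols), s))
})

setMethod("show", "BinScheme", function(object) {
  lab <- ifelse(object@lower == object@upper, object@lower,
                paste0(object@lower, "-", object@upper))
  cat(sprintf("BinScheme over [1, %d]: %s\n", object@maxRun,
              paste0("{", lab, "}", collapse = " ")))
})

setMethod("show", "RLEMatrix", function(object) {
  cat(sprintf("RLEMatrix %s '%s': %d x %d, n_r = %g, n_p = %g\n",
              object@kind, object@animalId, nrow(object@counts),
              ncol(object@counts), object@nRuns, object@nSteps))
})

setMethod("show", "WormClustering", function(object) {
  cat(sprintf("WormClustering: %d animals in %d clusters (features: %s)\n",
              length(object@assignment), object@k,
              paste(object@features, collapse = ", ")))
  print(table(group = object@groups, cluster = object@assignment))
})
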