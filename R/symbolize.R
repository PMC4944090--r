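# Step symbolization: pooled k-means over normalized step features,
# clusters relabeled to symbols by ascending mean raw angle.

.normFeatureNames <- c("lengthNorm", "angleNorm", "speedNorm")

# Pool angle-bearing steps across tables; keeps provenance columns.
.pooledAngleSteps <- function(tables) {
  do.call(rbind, lapply(tables, function(tb) {
    s <- tb@steps
    s <- s[!is.na(s$angleDeg), , drop = FALSE]
    if (!nrow(s)) return(NULL)
    cbind(animalId = tb@animalId, group = tb@group, s)
  }))
}

#' Fit the step-symbolization k-means model
#'
#' Pools the angle-bearing steps of all animals and clusters them by
#' k-means (Euclidean distance) on the normalized (length, angle, speed)
#' features, with a fixed seed and multiple restarts for reproducibility.
#' Clusters are then relabeled to symbols 1..k by ascending mean raw angle,
#' so the symbol semantics are invariant to k-means initialization: symbol
#' 1 is always the sharpest-turning cluster, and for k = 2, symbol 1 =
#' sharp turn (angle below ~90 degrees), symbol 2 = shallow turn.
#'
#' @param tables a list of normalized [StepTable-class] objects (see
#'   [normalizeFeatures()]).
#' @param k number of movement-pattern clusters, 2..5 (default 2).
#' @param seed integer RNG seed.
#' @param restarts number of k-means restarts (default 10).
#' @return a [StepClusterModel-class]; its `clusterRanges` slot reports the
#'   per-symbol min/max of the raw angle, length and speed.
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(4, 60, seed = 8))
#' fitStepClusters(tabs, k = 2, seed = 1)
#' @export
fitStepClusters <- function(tables, k = 2L, seed = 1L, restarts = 10L) {
  k <- as.integer(k)
  stopIfNot(k >= 2L && k <= 5L, "k must be in [2, 5]")
  stopIfNot(all(vapply(tables, function(tb) isTRUE(tb@normalized), TRUE)),
            "step tables must be normalized first (see normalizeFeatures)")
  pooled <- .pooledAngleSteps(tables)
  if (is.null(pooled) || nrow(pooled) < k)
    stop("need at least k angle-bearing steps to fit", call. = FALSE)
  x <- as.matrix(pooled[, .normFeatureNames])
  if (nrow(unique(x)) < k)
    stop(sprintf("degenerate clustering: only %d distinct step feature points for k = %d",
                 nrow(unique(x)), k), call. = FALSE)
  km <- withLocalSeed(seed,
    stats::kmeans(x, centers = k, nstart = restarts, iter.max = 300L,
                  algorithm = "Hartigan-Wong"))
  meanAngle <- tapply(pooled$angleDeg, km$cluster, mean)
  ord <- order(meanAngle)            # raw cluster ids in symbol order
  symbolOf <- integer(k)
  symbolOf[as.integer(names(meanAngle))[ord]] <- seq_len(k)
  sym <- symbolOf[km$cluster]

  rng <- do.call(rbind, lapply(seq_len(k), function(s) {
    sel <- sym == s
    data.frame(symbol = s,
               angleMin = min(pooled$angleDeg[sel]), angleMax = max(pooled$angleDeg[sel]),
               lengthMin = min(pooled$lengthMm[sel]), lengthMax = max(pooled$lengthMm[sel]),
               speedMin = min(pooled$speedMmS[sel]), speedMax = max(pooled$speedMmS[sel]))
  }))
  centers <- km$centers[as.integer(names(meanAngle))[ord], , drop = FALSE]
  rownames(centers) <- paste0("symbol", seq_len(k))
  new("StepClusterModel", k = k, centers = centers, clusterRanges = rng,
      seed = as.integer(seed))
}

#' Symbolize step tables with a fitted model
#'
#' Assigns every angle-bearing step to the symbol of its nearest model
#' centroid (Euclidean distance in normalized feature space), preserving
#' step order. Exact distance ties go to the lowest symbol id. Tables with
#' no angle-bearing steps yield an empty string with a warning.
#'
#' @param tables a list of normalized [StepTable-class] objects on the same
#'   normalization scale the model was fitted on.
#' @param model a [StepClusterModel-class].
#' @return a list of [SymbolString-class] objects, one per table.
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(2, 30, seed = 8))
#' mod <- fitStepClusters(tabs, k = 2, seed = 1)
#' symbols(symbolize(tabs, mod)[[1]])
#' @export
symbolize <- function(tables, model) {
  stopIfNot(is(model, "StepClusterModel"), "model must be a StepClusterModel")
  lapply(tables, function(tb) {
    s <- tb@steps[!is.na(tb@steps$angleDeg), , drop = FALSE]
    if (!nrow(s)) {
      warning(sprintf("animal '%s' has no angle-bearing steps; empty symbol string",
                      tb@animalId))
      return(new("SymbolString", animalId = tb@animalId, group = tb@group,
                 symbols = integer(), k = model@k))
    }
    x <- as.matrix(s[, .normFeatureNames])
    d2 <- vapply(seq_len(model@k), function(j)
      rowSums(sweep(x, 2, model@centers[j, ])^2), numeric(nrow(x)))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
    sym <- apply(d2, 1L, which.min)  # which.min takes the lowest index on ties
    new("SymbolString", animalId = tb@animalId, group = tb@group,
        symbols = as.integer(sym), k = model@k)
  })
}

#' Agreement between symbols and the 90-degree angle rule
#'
#' For a two-symbol model, computes the fraction of steps whose assigned
#' symbol matches the plain angle threshold rule: interior angle below 90
#' degrees is a sharp turn (symbol 1), otherwise a shallow turn (symbol 2).
#' High agreement confirms that the angle feature dominates the two-cluster
#' structure of the step data.
#'
#' @param strings a list of [SymbolString-class] objects (k = 2).
#' @param tables the matching list of [StepTable-class] objects, same order.
#' @return the agreement fraction in [0, 1].
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(4, 60, seed = 8))
#' mod <- fitStepClusters(tabs, k = 2, seed = 1)
#' angleRuleAgreement(symbolize(tabs, mod), tabs)
#' @export
angleRuleAgreement <- function(strings, tables) {
  stopIfNot(length(strings) == length(tables),
            "strings and tables must have the same length")
  if (any(vapply(strings, function(s) s@k, 1L) != 2L))
    stop("angle-rule agreement is defined for k = 2 only", call. = FALSE)
  agree <- 0L; total <- 0L
  for (i in seq_along(strings)) {
    ang <- tables[[i]]@steps$angleDeg
    ang <- ang[!is.na(ang)]
    sym <- strings[[i]]@symbols
    stopIfNot(length(ang) == length(sym),
              sprintf("symbol count mismatch for animal '%s'", strings[[i]]@animalId))
    ruleSym <- ifelse(ang < 90, 1L, 2L)
    agree <- agree + sum(ruleSym == sym)
    total <- total + length(sym)
  }
  if (total == 0L) stop("no angle-bearing steps", call. = FALSE)
  agree / total
}
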