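# Animal-level clustering by descriptor profiles and composition reporting.

#' Cluster animals by their run-length descriptor profiles
#'
#' Min-max scales the chosen descriptor columns over animals (the
#' descriptors span orders of magnitude, e.g. LRHAE versus RP) and runs
#' k-means with Euclidean distance, fixed seeding and multiple restarts.
#' Animals with similar movement-pattern composition and ordering land in
#' the same cluster.
#'
#' @param table a descriptor `data.frame` from [descriptorTable()].
#' @param features descriptor names to use; default all eleven.
#' @param k number of clusters (default 5, one per experimental condition
#'   in a typical on/off-food design).
#' @param seed integer RNG seed.
#' @param restarts number of k-means restarts.
#' @return a [WormClustering-class].
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(8, 60, seed = 2))
#' mod <- fitStepClusters(tabs, seed = 1)
#' dt <- descriptorTable(buildCohortMatrices(symbolize(tabs, mod), "BAMF"))
#' clusterWorms(dt, k = 2, seed = 1)
#' @export
clusterWorms <- function(table, features = rleDescriptorNames(), k = 5L,
                         seed = 1L, restarts = 10L) {
  k <- as.integer(k)
  stopIfNot(all(features %in% names(table)),
            "features must be descriptor columns of table")
  stopIfNot(k >= 1L, "k must be >= 1")
  if (k > nrow(table))
    stop(sprintf("k = %d exceeds the number of animals (%d)", k, nrow(table)),
         call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  x <- apply(x, 2, minMaxScale)
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(table))
  assign <- if (k == 1L) rep(1L, nrow(table)) else {
    km <- withLocalSeed(seed,
      stats::kmeans(x, centers = k, nstart = restarts, iter.max = 300L))
    as.integer(km$cluster)
  }
  names(assign) <- table$animalId
  groups <- as.character(table$group)
  names(groups) <- table$animalId
  new("WormClustering", k = k, assignment = assign, groups = groups,
      features = as.character(features), seed = as.integer(seed))
}

#' Cluster composition by group
#'
#' For every (group, cluster) pair reports two ratios: `clusterShare`, the
#' worms of that group in the cluster divided by the cluster size (cell
#' values summing to 1 within each cluster), and `groupShare`, the same
#' count divided by the group size (summing to 1 within each group).
#'
#' @param clustering a [WormClustering-class].
#' @return a `data.frame` with columns `group`, `cluster`, `count`,
#'   `clusterShare`, `groupShare`.
#' @examples
#' cl <- new("WormClustering", k = 2L,
#'           assignment = c(a = 1L, b = 1L, c = 2L),
#'           groups = c(a = "g1", b = "g2", c = "g2"),
#'           features = "RP", seed = 1L)
#' compositionTable(cl)
#' @export
compositionTable <- function(clustering) {
  stopIfNot(is(clustering, "WormClustering"), "need a WormClustering")
  g <- clustering@groups
  if (any(is.na(g) | g == ""))
    stop("every animal must carry a group label", call. = FALSE)
  a <- clustering@assignment
  tab <- table(group = g, cluster = factor(a, levels = seq_len(clustering@k)))
  df <- as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
  clusterSize <- as.numeric(tapply(df$count, df$cluster, sum)[as.character(df$cluster)])
  groupSize <- as.numeric(tapply(df$count, df$group, sum)[df$group])
  df$clusterShare <- ifelse(clusterSize > 0, df$count / clusterSize, 0)
  df$groupShare <- ifelse(groupSize > 0, df$count / groupSize, 0)
  df$cluster <- as.integer(as.character(df$cluster))
  df[order(df$group, df$cluster), ]
}

#' Clustering stability across seeds and matrix kinds
#'
#' Reruns [clusterWorms()] under `nSeeds` different seeds for each supplied
#' descriptor table (typically one per matrix kind) and returns the mean
#' pairwise adjusted Rand index across all runs — 1 when every run groups
#' the animals identically, near 0 for chance-level agreement. This probes
#' whether the grouping is an artifact of one matrix variant or seed.
#'
#' @param tables a named list of descriptor `data.frame`s (or a single
#'   `data.frame`), all covering the same animals in the same order.
#' @param features descriptor names to use, or `NULL` to select per table
#'   with [selectDescriptors()].
#' @param k number of clusters.
#' @param nSeeds number of seeds per table (>= 2).
#' @param baseSeed seed from which the run seeds are derived.
#' @return a list with `meanARI` and the per-run assignment matrix.
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(8, 60, seed = 2))
#' mod <- fitStepClusters(tabs, seed = 1)
#' dt <- descriptorTable(buildCohortMatrices(symbolize(tabs, mod), "BAMF"))
#' stabilityReport(dt, k = 2, nSeeds = 3)$meanARI
#' @export
stabilityReport <- function(tables, features = NULL, k = 2L, nSeeds = 5L,
                            baseSeed = 1L) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopIfNot(nSeeds >= 2, "nSeeds must be >= 2")
  seeds <- deriveSeeds(baseSeed, nSeeds)
  runs <- list()
  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    feats <- features
    if (is.null(feats)) feats <- selectDescriptors(tb)$kept
    for (s in seeds) {
      cl <- clusterWorms(tb, features = feats, k = k, seed = s)
      runs[[length(runs) + 1L]] <- cl@assignment
    }
  }
  A <- do.call(rbind, runs)
  nRun <- nrow(A)
  aris <- c()
  for (i in seq_len(nRun - 1L)) for (j in (i + 1L):nRun)
    aris <- c(aris, mclust::adjustedRandIndex(A[i, ], A[j, ]))
  list(meanARI = mean(aris), assignments = A)
}
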