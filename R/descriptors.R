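# The eleven run-length descriptors and the correlation filter.

#' Names of the eleven run-length descriptors
#'
#' Returns the descriptor names in their canonical order (also the scan
#' order of the greedy correlation filter in [selectDescriptors()]).
#'
#' @return a character vector of length 11.
#' @examples
#' rleDescriptorNames()
#' @export
rleDescriptorNames <- function() {
  c("SRE", "LRE", "LARE", "HARE", "SRLAE", "SRHAE", "LRLAE", "LRHAE",
    "ALN", "RLN", "RP")
}

#' Compute the eleven run-length descriptors of a matrix
#'
#' Evaluates, with i the symbol (row) index and j the column's run-length
#' value (`colValues`; bin index for BAMF, within-bin mean for BAAMF), and
#' n_r/n_p the total run and symbol counts:
#' \describe{
#'   \item{SRE / LRE}{short/long run emphasis, weights 1/j^2 and j^2 — the
#'     prevalence of brief versus sustained repeats of the same movement
#'     pattern.}
#'   \item{LARE / HARE}{low/high angle-level emphasis, weights 1/i^2 and
#'     i^2 — the prevalence of sharp (symbol 1) versus shallow (symbol 2)
#'     turning.}
#'   \item{SRLAE, SRHAE, LRLAE, LRHAE}{the four joint run-length/angle-level
#'     emphases with weights 1/(i^2 j^2), i^2/j^2, j^2/i^2 and i^2 j^2.}
#'   \item{ALN / RLN}{angle-level and run-length nonuniformity, the squared
#'     marginal sums (1/n_r) sum_i (sum_j P)^2 and (1/n_r) sum_j (sum_i P)^2
#'     — large when runs concentrate on few symbols / few run lengths.}
#'   \item{RP}{run percentage n_r / n_p, the homogeneity of the run
#'     distribution: 1 when every run has length 1, small when the path
#'     dwells in long uniform stretches.}
#' }
#' All sums run over the stored grid entries (transformed values for the
#' log kinds), divided by n_r.
#'
#' @param m a [RLEMatrix-class] with `nRuns >= 1`.
#' @return a named numeric vector of length 11.
#' @examples
#' rl <- runLengthEncode(c(2,2,1,2,2,2,2,1,2,2,2))
#' computeDescriptors(buildRLEMatrix(rl, "IMF", nSymbols = 2))
#' @export
computeDescriptors <- function(m) {
  stopIfNot(is(m, "RLEMatrix"), "m must be an RLEMatrix")
  if (m@nRuns < 1)
    stop(sprintf("descriptors are undefined for '%s': the matrix holds no runs",
                 m@animalId), call. = FALSE)
  P <- m@counts
  i2 <- seq_len(nrow(P))^2
  j2 <- m@colValues^2
  W <- outer(i2, j2)          # i^2 * j^2 weight grid
  nr <- m@nRuns
  c(SRE   = sum(sweep(P, 2, j2, "/")) / nr,
    LRE   = sum(sweep(P, 2, j2, "*")) / nr,
    LARE  = sum(P / i2) / nr,
    HARE  = sum(P * i2) / nr,
    SRLAE = sum(P / W) / nr,
    SRHAE = sum(sweep(P * i2, 2, j2, "/")) / nr,
    LRLAE = sum(sweep(P / i2, 2, j2, "*")) / nr,
    LRHAE = sum(P * W) / nr,
    ALN   = sum(rowSums(P)^2) / nr,
    RLN   = sum(colSums(P)^2) / nr,
    RP    = nr / m@nSteps)
}

#' Descriptor table for a cohort
#'
#' Computes the eleven descriptors for every animal's matrix and assembles
#' the per-animal feature table used for animal-level clustering.
#'
#' @param mats a list of [RLEMatrix-class] objects of one kind, e.g. from
#'   [buildCohortMatrices()].
#' @return a `data.frame` with columns `animalId`, `group`, `kind` and the
#'   eleven descriptors.
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(3, 40, seed = 2))
#' mod <- fitStepClusters(tabs, seed = 1)
#' mats <- buildCohortMatrices(symbolize(tabs, mod), "BAMF")
#' descriptorTable(mats)
#' @export
descriptorTable <- function(mats) {
  stopIfNot(is.list(mats) && length(mats) >= 1, "mats must be a non-empty list")
  rows <- lapply(mats, function(m) {
    d <- computeDescriptors(m)
    cbind(data.frame(animalId = m@animalId, group = m@group, kind = m@kind),
          as.data.frame(as.list(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy correlation filter over descriptors
#'
#' Several of the eleven descriptors are strongly redundant (e.g. the run
#' emphases and the joint emphases). Scanning the descriptors in their
#' canonical order ([rleDescriptorNames()]), a descriptor is kept iff its
#' absolute Pearson correlation across animals with every already-kept
#' descriptor is below `threshold`. Constant (zero-variance) descriptors
#' are dropped with a warning. The kept set therefore satisfies the
#' pairwise threshold by construction.
#'
#' @param table a descriptor `data.frame` from [descriptorTable()] (one
#'   matrix kind, at least 3 animals).
#' @param threshold correlation threshold (default 0.9).
#' @return a list with `kept` (ordered names), `dropped`, and `correlation`
#'   (the full descriptor correlation matrix).
#' @examples
#' tabs <- normalizeFeatures(simulateBimodalSteps(6, 60, seed = 2))
#' mod <- fitStepClusters(tabs, seed = 1)
#' mats <- buildCohortMatrices(symbolize(tabs, mod), "BAMF")
#' selectDescriptors(descriptorTable(mats))$kept
#' @export
selectDescriptors <- function(table, threshold = 0.9) {
  stopIfNot(threshold > 0, "threshold must be > 0")
  desc <- rleDescriptorNames()
  stopIfNot(all(desc %in% names(table)), "table is missing descriptor columns")
  if (nrow(table) < 3)
    stop("descriptor selection needs at least 3 animals", call. = FALSE)
  x <- as.matrix(table[, desc])
  sds <- apply(x, 2, stats::sd)
  constant <- desc[sds == 0]
  if (length(constant))
    warning(sprintf("constant descriptor(s) dropped: %s",
                    paste(constant, collapse = ", ")))
  usable <- setdiff(desc, constant)
  cm <- suppressWarnings(stats::cor(x))
  kept <- character()
  for (d in usable) {
    if (!length(kept) || all(abs(cm[d, kept]) < threshold)) kept <- c(kept, d)
  }
  list(kept = kept, dropped = setdiff(desc, kept), correlation = cm)
}
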