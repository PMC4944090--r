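# The eleven descriptors and the correlation filter.

test_that("a single run has closed-form descriptor values", {
  m <- buildRLEMatrix(runLengthEncode(c(2L, 2L, 2L, 2L)), "IMF", nSymbols = 2)
  d <- computeDescriptors(m)
  expect_equal(unname(d["SRE"]), 1 / 16)
  expect_equal(unname(d["LRE"]), 16)
  expect_equal(unname(d["LARE"]), 1 / 4)
  expect_equal(unname(d["HARE"]), 4)
  expect_equal(unname(d["SRLAE"]), 1 / 64)
  expect_equal(unname(d["SRHAE"]), 1 / 4)
  expect_equal(unname(d["LRLAE"]), 4)
  expect_equal(unname(d["LRHAE"]), 64)
  expect_equal(unname(d["ALN"]), 1)
  expect_equal(unname(d["RLN"]), 1)
  expect_equal(unname(d["RP"]), 0.25)
})

test_that("the example string matches the loop oracle, and RP = 5/11", {
  s <- as.integer(strsplit("22122221222", "")[[1]])
  m <- buildRLEMatrix(runLengthEncode(s), "IMF", nSymbols = 2)
  d <- computeDescriptors(m)
  expect_equal(unname(d["RP"]), 5 / 11)
  o <- oracleDescriptors(oracleRunCounts(s, 2), colValues(m), nRuns(m),
                         nSteps(m))
  expect_true(all(relDiff(d[names(o)], o) < 1e-12))
})

test_that("all-singleton runs collapse SRE, LRE and RP to 1", {
  m <- buildRLEMatrix(runLengthEncode(c(1L, 2L, 1L, 2L, 1L, 2L)), "IMF",
                      nSymbols = 2)
  d <- computeDescriptors(m)
  expect_equal(unname(d["SRE"]), 1)
  expect_equal(unname(d["LRE"]), 1)
  expect_equal(unname(d["RP"]), 1)
})

test_that("descriptors error when the matrix holds no runs", {
  m <- buildRLEMatrix(runLengthEncode(integer()), "IMF", nSymbols = 2)
  expect_error(computeDescriptors(m), "no runs")
})

test_that("scaling counts by c scales only the nonuniformity descriptors", {
  m <- buildRLEMatrix(runLengthEncode(c(1L, 1L, 2L, 1L, 2L, 2L, 2L)), "IMF",
                      nSymbols = 2)
  d1 <- computeDescriptors(m)
  m2 <- m
  m2@counts <- 3 * m@counts
  m2@nRuns <- 3 * m@nRuns
  m2@nSteps <- 3 * m@nSteps
  d3 <- computeDescriptors(m2)
  emph <- c("SRE", "LRE", "LARE", "HARE", "SRLAE", "SRHAE", "LRLAE", "LRHAE", "RP")
  expect_equal(d3[emph], d1[emph])
  expect_equal(unname(d3["ALN"]), unname(3 * d1["ALN"]))
  expect_equal(unname(d3["RLN"]), unname(3 * d1["RLN"]))
})

test_that("descriptors use the column values of binned and log variants", {
  s <- c(rep(1L, 5), 2L, rep(1L, 12), 2L, 2L)
  runs <- runLengthEncode(s)
  for (kind in c("BAMF", "BAAMF")) {
    m <- buildRLEMatrix(runs, kind, nSymbols = 2, globalMaxRun = 12)
    o <- oracleDescriptors(rleCounts(m), colValues(m), nRuns(m), nSteps(m))
    d <- computeDescriptors(m)
    expect_true(all(relDiff(d[names(o)], o) < 1e-12))
  }
  lm <- logTransform(buildRLEMatrix(runs, "IMF", nSymbols = 2))
  o <- oracleDescriptors(rleCounts(lm), colValues(lm), nRuns(lm), nSteps(lm))
  expect_true(all(relDiff(computeDescriptors(lm)[names(o)], o) < 1e-12))
})

test_that("the descriptor table has one row per animal and eleven columns", {
  strs <- list(makeSymbolString(c(1, 1, 2, 1), id = "a", group = "g1"),
               makeSymbolString(c(2, 2, 2, 1), id = "b", group = "g2"))
  dt <- descriptorTable(buildCohortMatrices(strs, "AMF"))
  expect_equal(nrow(dt), 2)
  expect_true(all(rleDescriptorNames() %in% names(dt)))
  expect_equal(dt$animalId, c("a", "b"))
  expect_equal(dt$kind, c("AMF", "AMF"))
})

.fakeDescTable <- function(x) {
  # wrap an 11-column matrix as a descriptor table
  colnames(x) <- rleDescriptorNames()
  cbind(data.frame(animalId = paste0("w", seq_len(nrow(x))), group = "g",
                   kind = "IMF"), as.data.frame(x))
}

test_that("greedy filter drops perfectly correlated and constant descriptors", {
  set.seed(1)
  x <- matrix(rnorm(10 * 11), 10, 11)
  x[, 2] <- 2 * x[, 1]          # LRE = 2 * SRE -> r = 1, LRE dropped
  x[, 5] <- 1                   # SRLAE constant -> dropped with warning
  expect_warning(sel <- selectDescriptors(.fakeDescTable(x)), "constant")
  expect_true("SRE" %in% sel$kept)
  expect_false("LRE" %in% sel$kept)
  expect_false("SRLAE" %in% sel$kept)
  # kept set satisfies the pairwise threshold by construction
  cm <- sel$correlation[sel$kept, sel$kept]
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.9))
  expect_error(selectDescriptors(.fakeDescTable(x[1:2, , drop = FALSE])),
               "3 animals")
})

test_that("independent descriptors all survive the 0.9 filter", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rnorm(200 * 11), 200, 11)
    sel <- selectDescriptors(.fakeDescTable(x))
    expect_equal(sel$kept, rleDescriptorNames())
  }
})

test_that("kept sets from real cohorts satisfy the threshold post hoc", {
  tabs <- normalizeFeatures(simulateBimodalSteps(12, 80, seed = 6))
  mod <- fitStepClusters(tabs, k = 2, seed = 1)
  strs <- symbolize(tabs, mod)
  for (kind in c("IMF", "BAMF", "AMFL")) {
    dt <- descriptorTable(buildCohortMatrices(strs, kind))
    sel <- suppressWarnings(selectDescriptors(dt))
    expect_gte(length(sel$kept), 1)
    if (length(sel$kept) > 1) {
      cm <- sel$correlation[sel$kept, sel$kept]
      expect_true(all(abs(cm[upper.tri(cm)]) < 0.9))
    }
  }
})
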