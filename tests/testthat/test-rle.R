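# Run-length encoding, bin schemes, and the matrix variants.

test_that("encoding compresses the documented example string into its runs", {
  s <- as.integer(strsplit("22122221222", "")[[1]])
  r <- runLengthEncode(s)
  expect_equal(r$symbol, c(2, 1, 2, 1, 2))
  expect_equal(r$runLength, c(2, 1, 4, 1, 3))
  expect_equal(runLengthEncode(c(1L, 1L, 1L)),
               data.frame(symbol = 1L, runLength = 3L))
  expect_equal(nrow(runLengthEncode(integer())), 0)
})

test_that("decoding inverts encoding exactly", {
  r <- data.frame(symbol = c(2, 1, 2, 1, 2), runLength = c(2, 1, 4, 1, 3))
  expect_equal(runLengthDecode(r), as.integer(strsplit("22122221222", "")[[1]]))
  expect_equal(runLengthDecode(data.frame(symbol = integer(),
                                          runLength = integer())), integer())
  expect_error(runLengthDecode(data.frame(symbol = 1, runLength = 0)), ">= 1")
  set.seed(5)
  for (i in 1:300) {
    s <- randomSymbolString(200, sample(2:5, 1))
    expect_identical(runLengthDecode(runLengthEncode(s)), s)
  }
})

test_that("bin schemes follow singleton-then-dyadic spans truncated at the maximum", {
  b <- makeBinScheme(37)
  expect_length(b@lower, 7)
  expect_equal(b@lower, c(1L, 2L, 3L, 4L, 9L, 17L, 33L))
  expect_equal(b@upper, c(1L, 2L, 3L, 8L, 16L, 32L, 37L))
  b3 <- makeBinScheme(3)
  expect_equal(b3@lower, 1:3)
  expect_equal(b3@upper, 1:3)
  b20 <- makeBinScheme(20)
  expect_equal(b20@lower, c(1L, 2L, 3L, 4L, 9L, 17L))
  expect_equal(b20@upper, c(1L, 2L, 3L, 8L, 16L, 20L))
  b64 <- makeBinScheme(64)
  expect_equal(b64@upper[length(b64@upper)], 64L)
  expect_equal(b64@lower[length(b64@lower)], 33L)
  expect_error(makeBinScheme(0), "maxRun")
})

test_that("IMF counts the example runs correctly", {
  runs <- runLengthEncode(as.integer(strsplit("22122221222", "")[[1]]))
  m <- buildRLEMatrix(runs, "IMF", nSymbols = 2)
  expect_equal(dim(rleCounts(m)), c(2, 4))
  expect_equal(unname(rleCounts(m)[1, ]), c(2, 0, 0, 0))
  expect_equal(unname(rleCounts(m)[2, ]), c(0, 1, 1, 1))
  expect_equal(nRuns(m), 5)
  expect_equal(nSteps(m), 11)
  expect_equal(colValues(m), 1:4)
})

test_that("AMF extends columns to the cohort maximum and checks overruns", {
  runs <- runLengthEncode(c(1L, 1L, 2L))
  m <- buildRLEMatrix(runs, "AMF", nSymbols = 2, globalMaxRun = 6)
  expect_equal(ncol(rleCounts(m)), 6)
  expect_equal(unname(rleCounts(m)[1, 2]), 1)
  expect_equal(unname(rleCounts(m)[2, 1]), 1)
  expect_error(buildRLEMatrix(runs, "AMF", nSymbols = 2, globalMaxRun = 1),
               "exceeds")
  expect_error(buildRLEMatrix(runs, "AMF", nSymbols = 2), "globalMaxRun")
})

test_that("BAMF aggregates the example into bins; BAAMF uses observed bin means", {
  runs <- runLengthEncode(as.integer(strsplit("22122221222", "")[[1]]))
  bins <- makeBinScheme(37)
  m <- buildRLEMatrix(runs, "BAMF", nSymbols = 2, globalMaxRun = 37, bins = bins)
  expect_equal(ncol(rleCounts(m)), 7)
  expect_equal(unname(rleCounts(m)[1, ]), c(2, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(rleCounts(m)[2, ]), c(0, 1, 1, 1, 0, 0, 0))
  expect_equal(colValues(m), 1:7)      # bin indices
  expect_equal(nRuns(m), 5)
  ma <- buildRLEMatrix(runs, "BAAMF", nSymbols = 2, globalMaxRun = 37, bins = bins)
  expect_equal(rleCounts(ma), rleCounts(m))  # same counts, different column values
  expect_equal(colValues(ma)[1:4], c(1, 2, 3, 4))  # observed means in bins 1-4
  expect_equal(colValues(ma)[5:7], c((9 + 16) / 2, (17 + 32) / 2, (33 + 37) / 2))
  expect_equal(ma@emptyBins, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  # binning conserves mass
  imf <- buildRLEMatrix(runs, "IMF", nSymbols = 2)
  expect_equal(sum(rleCounts(m)), sum(rleCounts(imf)))
})

test_that("empty strings yield empty matrices", {
  m <- buildRLEMatrix(runLengthEncode(integer()), "IMF", nSymbols = 2)
  expect_equal(sum(rleCounts(m)), 0)
  expect_equal(nRuns(m), 0)
  expect_equal(nSteps(m), 0)
})

test_that("log transform is ln(1+count), kind-checked, and order preserving", {
  runs <- runLengthEncode(c(rep(1L, 3), 2L, 1L, 2L, 2L))
  m <- buildRLEMatrix(runs, "IMF", nSymbols = 2)
  lm <- logTransform(m)
  expect_equal(lm@kind, "IMFL")
  expect_equal(rleCounts(lm), log1p(rleCounts(m)))
  expect_equal(nRuns(lm), nRuns(m))
  expect_equal(nSteps(lm), nSteps(m))
  # zero stays zero, e-1 maps to 1
  m0 <- m; m0@counts[] <- 0
  expect_true(all(rleCounts(logTransform(m0)) == 0))
  m1 <- m; m1@counts[] <- exp(1) - 1
  expect_equal(unname(rleCounts(logTransform(m1))[1, 1]), 1)
  # monotone and order preserving entrywise
  a <- c(rleCounts(m))
  expect_equal(rank(c(rleCounts(lm))), rank(a))
  # not applicable twice or to binned kinds
  expect_error(logTransform(lm), "IMF/AMF")
  bm <- buildRLEMatrix(runs, "BAMF", nSymbols = 2, globalMaxRun = 3)
  expect_error(logTransform(bm), "IMF/AMF")
})

test_that("conservation laws hold on random strings", {
  set.seed(99)
  for (i in 1:200) {
    s <- randomSymbolString(300, sample(2:5, 1))
    if (!length(s)) next
    k <- max(s)
    m <- buildRLEMatrix(runLengthEncode(s), "IMF", nSymbols = k)
    P <- rleCounts(m)
    expect_equal(sum(sweep(P, 2, colValues(m), "*")), length(s))
    expect_equal(sum(P), oracleRunTotal(s))
    # binning conserves the run count
    b <- buildRLEMatrix(runLengthEncode(s), "BAMF", nSymbols = k,
                        globalMaxRun = max(runLengthEncode(s)$runLength))
    expect_equal(sum(rleCounts(b)), sum(P))
  }
})

test_that("cohort matrices share the global maximum and bin scheme", {
  strs <- list(makeSymbolString(c(1, 1, 1, 1, 1, 2), id = "a"),
               makeSymbolString(c(2, 1), id = "b"))
  amf <- buildCohortMatrices(strs, "AMF")
  expect_equal(ncol(rleCounts(amf$a)), 5)
  expect_equal(ncol(rleCounts(amf$b)), 5)
  bamf <- buildCohortMatrices(strs, "BAMF")
  expect_equal(colValues(bamf$a), colValues(bamf$b))
  lg <- buildCohortMatrices(strs, "AMFL")
  expect_equal(lg$a@kind, "AMFL")
  expect_equal(rleCounts(lg$a), log1p(rleCounts(amf$a)))
})
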