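# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no rle(), no matrix algebra): runs are counted by scanning the
# raw string position by position, and descriptors are accumulated entry by
# entry in explicit loops.

# Maximum maximal-run length in s, by direct scan.
oracleMaxRun <- function(s) {
  n <- length(s)
  if (!n) return(0L)
  best <- 1L; cur <- 1L
  for (t in 2:max(2, n)) {
    if (t > n) break
    if (s[t] == s[t - 1]) cur <- cur + 1L else cur <- 1L
    best <- max(best, cur)
  }
  best
}

# P[i, j] = number of maximal runs of symbol i with exact length j,
# counted by checking every candidate start position.
oracleRunCounts <- function(s, nSymbols, maxJ = oracleMaxRun(s)) {
  P <- matrix(0, nSymbols, max(maxJ, 1L))
  n <- length(s)
  if (!n) return(P[, 0, drop = FALSE])
  for (i in seq_len(nSymbols)) {
    for (j in seq_len(maxJ)) {
      for (t in seq_len(n)) {
        if (s[t] != i) next
        if (t + j - 1L > n) next
        if (any(s[t:(t + j - 1L)] != i)) next
        if (t > 1L && s[t - 1L] == i) next                  # not a run start
        if (t + j <= n && s[t + j] == i) next               # not maximal
        P[i, j] <- P[i, j] + 1
      }
    }
  }
  P
}

# Total number of maximal runs, by direct scan.
oracleRunTotal <- function(s) {
  n <- length(s)
  if (!n) return(0L)
  cnt <- 1L
  for (t in 2:max(2, n)) {
    if (t > n) break
    if (s[t] != s[t - 1]) cnt <- cnt + 1L
  }
  cnt
}

# The eleven descriptors accumulated entry by entry.
oracleDescriptors <- function(P, colVals, nr, np) {
  dimnames(P) <- NULL
  colVals <- unname(colVals)
  M <- nrow(P); N <- ncol(P)
  sre <- lre <- lare <- hare <- srlae <- srhae <- lrlae <- lrhae <- 0
  for (i in seq_len(M)) for (jc in seq_len(N)) {
    p <- P[i, jc]; j <- colVals[jc]
    sre <- sre + p / j^2;           lre <- lre + p * j^2
    lare <- lare + p / i^2;         hare <- hare + p * i^2
    srlae <- srlae + p / (i^2 * j^2); srhae <- srhae + p * i^2 / j^2
    lrlae <- lrlae + p * j^2 / i^2;   lrhae <- lrhae + p * i^2 * j^2
  }
  aln <- 0
  for (i in seq_len(M)) {
    rs <- 0
    for (jc in seq_len(N)) rs <- rs + P[i, jc]
    aln <- aln + rs^2
  }
  rln <- 0
  for (jc in seq_len(N)) {
    cs <- 0
    for (i in seq_len(M)) cs <- cs + P[i, jc]
    rln <- rln + cs^2
  }
  c(SRE = sre, LRE = lre, LARE = lare, HARE = hare, SRLAE = srlae,
    SRHAE = srhae, LRLAE = lrlae, LRHAE = lrhae, ALN = aln, RLN = rln,
    RP = nr / np) / c(rep(nr, 10), 1)
}

# Random symbol string over a given alphabet (length may be 0).
randomSymbolString <- function(maxLen = 500, alphabet = 2L) {
  n <- sample(0:maxLen, 1)
  if (!n) return(integer())
  sample.int(alphabet, n, replace = TRUE)
}

relDiff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)
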