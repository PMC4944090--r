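# Small constructors for hand-crafted geometry and step fixtures.

makeTrajectory <- function(x, y, t = seq_along(x) - 1, id = "w1", group = "g") {
  new("WormTrajectory", animalId = id, group = group,
      samples = data.frame(t = t, x = x, y = y))
}

makeSampledPath <- function(x, y, t = seq_along(x) - 1, deltaTs = 1, id = "w1") {
  new("SampledPath", animalId = id, group = "g",
      points = data.frame(t = t, x = x, y = y), deltaTs = deltaTs)
}

makeEvents <- function(x, y, t = seq_along(x) - 1, id = "w1") {
  new("TurningEvents", animalId = id, group = "g",
      events = data.frame(teIndex = seq_along(x) - 1L, t = t, x = x, y = y),
      thetaDeg = 40)
}

# A StepTable built directly from feature vectors (angles[1] is the
# first, angle-free step when NA).
makeStepTable <- function(lengths, angles, speeds, id = "w1", group = "g",
                          normalized = FALSE) {
  n <- length(lengths)
  tEnd <- cumsum(lengths / speeds)
  new("StepTable", animalId = id, group = group,
      steps = data.frame(stepIdx = seq_len(n), tStart = c(0, tEnd[-n]),
                         tEnd = tEnd, lengthMm = lengths, angleDeg = angles,
                         speedMmS = speeds, lengthNorm = NA_real_,
                         angleNorm = NA_real_, speedNorm = NA_real_),
      normalized = normalized, degenerateFeatures = character())
}

makeSymbolString <- function(sym, k = 2L, id = "w1", group = "g") {
  new("SymbolString", animalId = id, group = group,
      symbols = as.integer(sym), k = as.integer(k))
}

# Zigzag path: first segment due east, then headings alternating +/- devDeg
# about east, unit-length segments.
makeZigzag <- function(nSeg = 12, devDeg = 30) {
  h <- c(0, rep(c(devDeg, -devDeg), length.out = nSeg - 1)) * pi / 180
  makeSampledPath(c(0, cumsum(cos(h))), c(0, cumsum(sin(h))))
}
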