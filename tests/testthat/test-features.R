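# Resampling, turning-event detection, step features, normalization.

test_that("resampling interpolates linearly onto the grid", {
  # two raw samples (t=0,x=0) and (t=2,x=4) -> grid point (t=1, x=2)
  tr <- makeTrajectory(x = c(0, 4), y = c(0, 0), t = c(0, 2))
  sp <- resamplePath(tr, 1)
  expect_equal(sp@points$t, c(0, 1, 2))
  expect_equal(sp@points$x, c(0, 2, 4))
  # samples already on the grid are returned unchanged
  tr2 <- makeTrajectory(x = 0:5, y = (0:5)^2, t = 0:5)
  sp2 <- resamplePath(tr2, 1)
  expect_equal(sp2@points$x, 0:5)
  expect_equal(sp2@points$y, (0:5)^2)
  # 30 Hz straight line stays collinear after resampling
  tr3 <- makeTrajectory(x = seq(0, 3, by = 1/30), y = seq(0, 6, by = 2/30),
                        t = seq(0, 3, by = 1/30))
  sp3 <- resamplePath(tr3, 1)
  expect_equal(nrow(sp3@points), 4)
  expect_equal(sp3@points$y, 2 * sp3@points$x)
  expect_error(resamplePath(makeTrajectory(x = c(0, 1), y = c(0, 0),
                                           t = c(0, 0.5)), 1), "shorter")
})

test_that("turning events follow the threshold rule", {
  # collinear: only the initial event
  sp <- makeSampledPath(x = 0:9, y = rep(0, 10))
  te <- detectTurningEvents(sp, 40)
  expect_equal(nrow(te@events), 1)
  expect_equal(te@events$teIndex, 0L)
  # east then north: initial + the corner-adjacent point
  sp2 <- makeSampledPath(x = c(0:4, rep(4, 5)), y = c(rep(0, 5), 1:5))
  te2 <- detectTurningEvents(sp2, 40)
  expect_equal(nrow(te2@events), 2)
  expect_equal(te2@events$x[2], 4)
  expect_equal(te2@events$y[2], 1)
  # zigzag within +/-30 degrees of the initial heading: no event at theta=40
  te3 <- detectTurningEvents(makeZigzag(12, 30), 40)
  expect_equal(nrow(te3@events), 1)
  # ... but a 40-degree threshold does catch a +/-50 zigzag
  te4 <- detectTurningEvents(makeZigzag(12, 50), 40)
  expect_gt(nrow(te4@events), 1)
  # stationary path: initial event only, with a warning
  expect_warning(
    te5 <- detectTurningEvents(makeSampledPath(x = rep(1, 5), y = rep(2, 5))),
    "never moves")
  expect_equal(nrow(te5@events), 1)
})

test_that("zero-displacement intervals inherit the previous heading", {
  # pause in the middle of a straight run must not fabricate an event
  sp <- makeSampledPath(x = c(0, 1, 2, 2, 2, 3, 4), y = rep(0, 7))
  expect_equal(nrow(detectTurningEvents(sp, 40)@events), 1)
})

test_that("step geometry matches the interior-angle convention", {
  # collinear continuation -> 180 (shallow extreme)
  st <- computeSteps(makeEvents(x = c(0, 1, 2), y = c(0, 0, 0)))
  expect_equal(steps(st)$angleDeg, c(NA, 180))
  # perpendicular -> 90
  st2 <- computeSteps(makeEvents(x = c(0, 1, 1), y = c(0, 0, 1)))
  expect_equal(steps(st2)$angleDeg[2], 90)
  # full reversal -> 0
  st3 <- computeSteps(makeEvents(x = c(0, 1, 0), y = c(0, 0, 0)))
  expect_equal(steps(st3)$angleDeg[2], 0)
  # speed = displacement / elapsed time: 1.5 mm over 3 s -> 0.5 mm/s
  st4 <- computeSteps(makeEvents(x = c(0, 1.5), y = c(0, 0), t = c(2, 5)))
  expect_equal(steps(st4)$speedMmS, 0.5)
  expect_equal(steps(st4)$lengthMm, 1.5)
  # fewer than 2 events -> empty table with warning
  ev <- new("TurningEvents", animalId = "w", group = "g",
            events = data.frame(teIndex = 0L, t = 0, x = 0, y = 0),
            thetaDeg = 40)
  expect_warning(st5 <- computeSteps(ev), "fewer than 2")
  expect_equal(nrow(steps(st5)), 0)
})

test_that("step time intervals tile the event span and angles are geometric invariants", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- simulateWormPath(sharpTurnParams(seed = rep, durationS = 90))
    te <- detectTurningEvents(resamplePath(tr))
    st <- computeSteps(te)
    s <- steps(st)
    # conservation of time
    expect_equal(sum(s$tEnd - s$tStart),
                 te@events$t[nrow(te@events)] - te@events$t[1])
    # reflection about the x axis leaves angles unchanged
    ref <- te
    ref@events$y <- -ref@events$y
    expect_equal(steps(computeSteps(ref))$angleDeg, s$angleDeg)
    # scaling coordinates by c scales lengths and speeds, not angles
    sc <- te
    sc@events$x <- 3 * sc@events$x; sc@events$y <- 3 * sc@events$y
    s3 <- steps(computeSteps(sc))
    expect_equal(s3$lengthMm, 3 * s$lengthMm)
    expect_equal(s3$speedMmS, 3 * s$speedMmS)
    expect_equal(s3$angleDeg, s$angleDeg)
  }
})

test_that("min-max normalization pools across animals and guards zero ranges", {
  t1 <- makeStepTable(lengths = c(1, 1), angles = c(NA, 50), speeds = c(0.2, 0.5),
                      id = "a")
  t2 <- makeStepTable(lengths = c(3, 2), angles = c(NA, 130), speeds = c(0.8, 0.5),
                      id = "b")
  out <- normalizeFeatures(list(t1, t2))
  # pooled lengths {1,1,3,2}: min 1 max 3
  expect_equal(steps(out[[1]])$lengthNorm, c(0, 0))
  expect_equal(steps(out[[2]])$lengthNorm, c(1, 0.5))
  # pooled speeds {0.2,0.5,0.8,0.5}: middle maps to 0.5
  expect_equal(steps(out[[1]])$speedNorm[2], 0.5)
  # angles use only angle-bearing steps
  expect_equal(steps(out[[1]])$angleNorm, c(NA, 0))
  expect_equal(steps(out[[2]])$angleNorm, c(NA, 1))
  expect_true(all(vapply(out, function(tb) tb@normalized, TRUE)))
  # constant angle -> normalized to 0 with a degenerate-feature flag
  t3 <- makeStepTable(lengths = c(1, 2), angles = c(NA, 90), speeds = c(0.1, 0.2))
  t4 <- makeStepTable(lengths = c(2, 4), angles = c(NA, 90), speeds = c(0.3, 0.4))
  expect_warning(out2 <- normalizeFeatures(list(t3, t4)), "zero-range")
  expect_equal(steps(out2[[1]])$angleNorm[2], 0)
  expect_true("angleDeg" %in% out2[[1]]@degenerateFeatures)
})

test_that("raising the threshold never adds turning events on simulated paths", {
  thetas <- c(20, 40, 60, 80)
  set.seed(7)
  for (i in 1:25) {
    p <- simParams(durationS = 60,
                   pRoamToTurn = runif(1, 0.05, 0.5),
                   roamHeadingSdDeg = runif(1, 0, 20),
                   turnAngleMinDeg = runif(1, 30, 90),
                   turnAngleMaxDeg = runif(1, 90, 180),
                   seed = i)
    sp <- resamplePath(simulateWormPath(p))
    counts <- vapply(thetas, function(th)
      nrow(detectTurningEvents(sp, th)@events), 1L)
    expect_true(all(diff(counts) <= 0))
  }
})
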