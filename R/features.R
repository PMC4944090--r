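#' Resample a trajectory onto a regular time grid
#'
#' Samples the centroid track at a regular interval `deltaTs` (default 1 s),
#' linearly interpolating between the two bracketing raw frames. The grid
#' starts at the first raw timestamp and its last point does not exceed the
#' last raw timestamp. Resampling trades noise reduction against fidelity:
#' a coarser grid suppresses frame-level tracking noise.
#'
#' @param traj a [WormTrajectory-class].
#' @param deltaTs grid interval in seconds.
#' @return a [SampledPath-class].
#' @examples
#' tr <- simulateWormPath(simParams(durationS = 10, seed = 1))
#' sp <- resamplePath(tr)
#' nrow(sp@points)
#' @export
resamplePath <- function(traj, deltaTs = 1.0) {
  validObject(traj)
  stopIfNot(deltaTs > 0, "deltaTs must be > 0")
  s <- traj@samples
  span <- s$t[nrow(s)] - s$t[1]
  if (span < 2 * deltaTs)
    stop(sprintf("trajectory '%s' spans %.3f s, shorter than 2 * deltaTs = %.3f s",
                 traj@animalId, span, 2 * deltaTs), call. = FALSE)
  grid <- s$t[1] + deltaTs * seq.int(0L, floor(span / deltaTs + 1e-9))
  pts <- data.frame(
    t = grid,
    x = stats::approx(s$t, s$x, xout = grid)$y,
    y = stats::approx(s$t, s$y, xout = grid)$y)
  new("SampledPath", animalId = traj@animalId, group = traj@group,
      points = pts, deltaTs = deltaTs)
}

# Reference-heading rule: the heading attached to a turning event is the
# direction of the first displacement leaving it. Kept in one place so the
# alternative convention (incoming / segment-mean heading) can be swapped.
.postEventHeading <- function(headings, eventIdx) {
  if (eventIdx + 1L <= length(headings)) headings[eventIdx + 1L] else NA_real_
}

#' Detect turning events along a sampled path
#'
#' Scans the regular-grid path and flags a point as a turning event when
#' the current movement heading (direction of the displacement into the
#' point) deviates by more than `thetaDeg` from the reference heading, the
#' direction of the first displacement leaving the previous turning event.
#' The first sampled point is always the initial turning event, and the
#' reference resets at every new event. Zero-displacement intervals inherit
#' the previous heading, so a stationary stretch never fabricates an event.
#'
#' The default threshold of 40 degrees sits above the roughly +/-30 degree
#' heading fluctuation of an animal moving straight, so straight locomotion
#' is not fragmented.
#'
#' @param path a [SampledPath-class].
#' @param thetaDeg detection threshold, strictly between 0 and 180 degrees.
#' @return a [TurningEvents-class].
#' @examples
#' tr <- simulateWormPath(sharpTurnParams(seed = 2, durationS = 60))
#' te <- detectTurningEvents(resamplePath(tr))
#' te
#' @export
detectTurningEvents <- function(path, thetaDeg = 40) {
  validObject(path)
  stopIfNot(thetaDeg > 0 && thetaDeg < 180, "thetaDeg must be in (0, 180)")
  p <- path@points
  n <- nrow(p)

  dx <- diff(p$x); dy <- diff(p$y)
  moved <- (dx != 0 | dy != 0)
  headings <- rep(NA_real_, n - 1L)
  raw <- atan2(dy, dx) * 180 / pi
  last <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (moved[i]) last <- raw[i]
    headings[i] <- last  # zero displacement inherits the previous heading
  }

  eventIdx <- 1L  # row indices into p; p[1] is the initial event
  if (all(!moved)) {
    warning(sprintf("path '%s' never moves; only the initial turning event returned",
                    path@animalId))
  } else {
    ref <- .postEventHeading(headings, 0L)  # heading out of the initial event
    for (i in 2:n) {
      h <- headings[i - 1L]  # heading into point i
      if (is.na(h) || is.na(ref)) next
      if (circularDiffDeg(h, ref) > thetaDeg) {
        eventIdx <- c(eventIdx, i)
        ref <- .postEventHeading(headings, i - 1L)
      }
    }
  }
  ev <- data.frame(teIndex = seq_along(eventIdx) - 1L,
                   t = p$t[eventIdx], x = p$x[eventIdx], y = p$y[eventIdx])
  new("TurningEvents", animalId = path@animalId, group = path@group,
      events = ev, thetaDeg = thetaDeg)
}

#' Compute the step table from turning events
#'
#' A step is the line segment between two consecutive turning events. Its
#' length is the displacement (mm) between the events, its speed that
#' displacement divided by the elapsed time, and its angle the interior
#' angle (degrees) at its starting event between the vector back to the
#' previous event and the vector forward to the next one: 180 degrees is
#' straight continuation, 0 a full reversal, below 90 a sharp turn and 90
#' or above a shallow turn. The first step of a path has no preceding step
#' and hence no angle (`NA`); it is retained for bookkeeping but excluded
#' from symbolization.
#'
#' @param events a [TurningEvents-class].
#' @return a [StepTable-class] (normalized columns `NA` until
#'   [normalizeFeatures()] is applied). Fewer than two events yield an
#'   empty table with a warning.
#' @examples
#' tr <- simulateWormPath(sharpTurnParams(seed = 2, durationS = 60))
#' st <- computeSteps(detectTurningEvents(resamplePath(tr)))
#' head(steps(st))
#' @export
computeSteps <- function(events) {
  validObject(events)
  e <- events@events
  emptySteps <- data.frame(
    stepIdx = integer(), tStart = numeric(), tEnd = numeric(),
    lengthMm = numeric(), angleDeg = numeric(), speedMmS = numeric(),
    lengthNorm = numeric(), angleNorm = numeric(), speedNorm = numeric())
  if (nrow(e) < 2) {
    warning(sprintf("animal '%s': fewer than 2 turning events, empty step table",
                    events@animalId))
    return(new("StepTable", animalId = events@animalId, group = events@group,
               steps = emptySteps, normalized = FALSE,
               degenerateFeatures = character()))
  }
  m <- nrow(e) - 1L  # number of steps
  vx <- diff(e$x); vy <- diff(e$y)
  len <- sqrt(vx^2 + vy^2)
  dt <- diff(e$t)
  spd <- len / dt

  ang <- rep(NA_real_, m)
  if (m >= 2) {
    for (j in 2:m) {
      # interior angle at event j (0-based: the event between steps j-1 and j)
      ux <- -vx[j - 1L]; uy <- -vy[j - 1L]   # back toward the previous event
      wx <- vx[j]; wy <- vy[j]               # forward to the next event
      nu <- sqrt(ux^2 + uy^2); nw <- sqrt(wx^2 + wy^2)
      if (nu == 0 || nw == 0) next           # degenerate zero-length step
      cosA <- (ux * wx + uy * wy) / (nu * nw)
      ang[j] <- acos(pmin(1, pmax(-1, cosA))) * 180 / pi
    }
  }
  new("StepTable", animalId = events@animalId, group = events@group,
      steps = data.frame(
        stepIdx = seq_len(m), tStart = e$t[-(m + 1L)], tEnd = e$t[-1L],
        lengthMm = len, angleDeg = ang, speedMmS = spd,
        lengthNorm = NA_real_, angleNorm = NA_real_, speedNorm = NA_real_),
      normalized = FALSE, degenerateFeatures = character())
}

#' Min-max normalize step features, pooled across animals
#'
#' Rescales length, angle and speed to [0, 1] so the three features carry
#' equal weight in the Euclidean distance used by step clustering. The
#' minimum and maximum of each feature are taken over ALL steps pooled
#' across every animal in the list, so all animals share one scale. A
#' feature whose pooled range is zero maps to 0 everywhere and is recorded
#' in the `degenerateFeatures` slot of each table (with a warning).
#'
#' @param tables a list of [StepTable-class] objects.
#' @return the same list with `lengthNorm`, `angleNorm`, `speedNorm` filled
#'   and `normalized = TRUE`.
#' @examples
#' tabs <- simulateBimodalSteps(2, 20, seed = 3)
#' tabs <- normalizeFeatures(tabs)
#' range(steps(tabs[[1]])$angleNorm, na.rm = TRUE)
#' @export
normalizeFeatures <- function(tables) {
  stopIfNot(is.list(tables) && length(tables) >= 1, "tables must be a non-empty list")
  feats <- c(lengthMm = "lengthNorm", angleDeg = "angleNorm", speedMmS = "speedNorm")
  pooled <- do.call(rbind, lapply(tables, function(tb) tb@steps[names(feats)]))
  if (sum(stats::complete.cases(pooled["lengthMm"])) < 2 || nrow(pooled) < 2)
    stop("need at least 2 pooled steps to normalize", call. = FALSE)
  degenerate <- character()
  lims <- lapply(names(feats), function(f) {
    v <- pooled[[f]]
    v <- v[is.finite(v)]
    if (!length(v)) stop(sprintf("feature %s has no finite values", f), call. = FALSE)
    lo <- min(v); hi <- max(v)
    if (hi == lo) degenerate <<- c(degenerate, f)
    c(lo, hi)
  })
  names(lims) <- names(feats)
  if (length(degenerate))
    warning(sprintf("zero-range feature(s) mapped to 0: %s",
                    paste(degenerate, collapse = ", ")))
  lapply(tables, function(tb) {
    s <- tb@steps
    for (f in names(feats))
      s[[feats[[f]]]] <- minMaxScale(s[[f]], lims[[f]][1], lims[[f]][2])
    tb@steps <- s
    tb@normalized <- TRUE
    tb@degenerateFeatures <- degenerate
    tb
  })
}

#' Trajectory to normalized step tables in one call
#'
#' Convenience wrapper chaining [resamplePath()], [detectTurningEvents()],
#' [computeSteps()] and pooled [normalizeFeatures()] over a list of
#' trajectories.
#'
#' @param trajs a list of [WormTrajectory-class] objects.
#' @param deltaTs resampling interval in seconds.
#' @param thetaDeg turning-event threshold in degrees.
#' @return a list of normalized [StepTable-class] objects.
#' @examples
#' coh <- simulateCohort(list(
#'   list(group = "sharp", params = sharpTurnParams(durationS = 60), nAnimals = 2)
#' ), seed = 4)
#' tabs <- extractSteps(coh)
#' tabs[[1]]
#' @export
extractSteps <- function(trajs, deltaTs = 1.0, thetaDeg = 40) {
  tabs <- lapply(trajs, function(tr)
    computeSteps(detectTurningEvents(resamplePath(tr, deltaTs), thetaDeg)))
  normalizeFeatures(tabs)
}
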