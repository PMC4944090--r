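#' Construct simulation parameters
#'
#' Builds a validated [SimParams-class] object for [simulateWormPath()].
#' Defaults emulate a single crawling animal filmed at 30 frames per second,
#' with modest heading jitter while roaming and occasional second-long
#' turning bouts.
#'
#' @param durationS track duration in seconds.
#' @param frameRateHz frames per second.
#' @param speedMeanMmS,speedSdMmS per-frame speed distribution (mm/s),
#'   Gaussian truncated at zero.
#' @param pRoamToTurn,pTurnToRoam per-second probabilities of switching
#'   regime, in [0, 1].
#' @param roamHeadingSdDeg per-second heading jitter (degrees) while roaming.
#' @param turnAngleMinDeg,turnAngleMaxDeg magnitude range (degrees) of the
#'   reorientation drawn each second while turning; direction is a fair
#'   coin, and magnitudes near 180 realize reversals.
#' @param seed integer RNG seed.
#' @return a [SimParams-class] object.
#' @examples
#' p <- simParams(durationS = 60, seed = 7)
#' tr <- simulateWormPath(p)
#' tr
#' @export
simParams <- function(durationS = 300, frameRateHz = 30,
                      speedMeanMmS = 0.15, speedSdMmS = 0.03,
                      pRoamToTurn = 0.1, pTurnToRoam = 0.5,
                      roamHeadingSdDeg = 10,
                      turnAngleMinDeg = 100, turnAngleMaxDeg = 180,
                      seed = 1L) {
  new("SimParams",
      durationS = as.numeric(durationS), frameRateHz = as.numeric(frameRateHz),
      speedMeanMmS = as.numeric(speedMeanMmS), speedSdMmS = as.numeric(speedSdMmS),
      pRoamToTurn = as.numeric(pRoamToTurn), pTurnToRoam = as.numeric(pTurnToRoam),
      roamHeadingSdDeg = as.numeric(roamHeadingSdDeg),
      turnAngleMinDeg = as.numeric(turnAngleMinDeg),
      turnAngleMaxDeg = as.numeric(turnAngleMaxDeg),
      seed = as.integer(seed))
}

#' Preset parameters for the two synthetic phenotypes
#'
#' Two calibrations of [simParams()] producing the qualitative sharp/shallow
#' dichotomy the pipeline is designed to detect. `sharpTurnParams()` turns
#' often and re-orients by 100-180 degrees, so most detected steps meet the
#' previous step at an interior angle below 90 degrees (sharp turns,
#' off-food-like searching). `shallowTurnParams()` turns rarely and gently
#' (45-80 degrees), so detected turns are predominantly shallow
#' (on-food-like dwelling/gliding).
#'
#' @param seed integer RNG seed.
#' @param durationS track duration in seconds.
#' @return a [SimParams-class] object.
#' @examples
#' sharpTurnParams(seed = 1)
#' @export
sharpTurnParams <- function(seed = 1L, durationS = 300) {
  simParams(durationS = durationS, pRoamToTurn = 0.45, pTurnToRoam = 0.5,
            roamHeadingSdDeg = 8, turnAngleMinDeg = 100, turnAngleMaxDeg = 180,
            seed = seed)
}

#' @rdname sharpTurnParams
#' @export
shallowTurnParams <- function(seed = 1L, durationS = 300) {
  simParams(durationS = durationS, pRoamToTurn = 0.08, pTurnToRoam = 0.8,
            roamHeadingSdDeg = 8, turnAngleMinDeg = 45, turnAngleMaxDeg = 80,
            seed = seed)
}

#' Simulate a single centroid trajectory
#'
#' Generates a synthetic single-animal centroid track from a two-regime
#' discrete-time process. On a 1-second clock the regime first updates
#' (roam to turn with probability `pRoamToTurn`, turn back to roam with
#' `pTurnToRoam`), then the heading updates under the new regime: a uniform
#' reorientation of magnitude in `[turnAngleMinDeg, turnAngleMaxDeg]` (sign
#' a fair coin) every second spent turning, or Gaussian jitter of sd
#' `roamHeadingSdDeg` while roaming. Between clock ticks the centroid
#' advances one frame at a time along the current heading, each frame's
#' displacement being a truncated-Gaussian speed divided by the frame rate.
#' Identical parameters (including `seed`) give bitwise-identical tracks.
#'
#' @param params a [SimParams-class] object.
#' @param animalId,group identifiers attached to the output.
#' @return a [WormTrajectory-class] with
#'   `durationS * frameRateHz + 1` samples.
#' @examples
#' tr <- simulateWormPath(simParams(durationS = 30, seed = 42))
#' nrow(samples(tr))
#' @export
simulateWormPath <- function(params, animalId = "sim1", group = "sim") {
  validObject(params)
  withLocalSeed(params@seed, {
    nSec <- as.integer(round(params@durationS))
    fps <- as.integer(round(params@frameRateHz))
    stopIfNot(nSec >= 1, "durationS must round to at least 1 second")
    stopIfNot(fps >= 1, "frameRateHz must round to at least 1 frame/s")

    # Per-second regime (TRUE = turn) and heading, updated regime-first.
    turning <- logical(nSec)
    heading <- numeric(nSec)
    h <- runif(1, 0, 360)
    state <- FALSE
    for (s in seq_len(nSec)) {
      state <- if (state) runif(1) >= params@pTurnToRoam
               else runif(1) < params@pRoamToTurn
      if (s == 1L) {
        # the first second keeps the initial roaming heading
        state <- FALSE
      } else if (state) {
        mag <- runif(1, params@turnAngleMinDeg, params@turnAngleMaxDeg)
        h <- h + sample(c(-1, 1), 1) * mag
      } else {
        h <- h + rnorm(1, 0, params@roamHeadingSdDeg)
      }
      turning[s] <- state
      heading[s] <- h
    }

    nFrames <- nSec * fps
    speeds <- pmax(0, rnorm(nFrames, params@speedMeanMmS, params@speedSdMmS))
    hRad <- rep(heading, each = fps) * pi / 180
    dx <- speeds / fps * cos(hRad)
    dy <- speeds / fps * sin(hRad)
    new("WormTrajectory", animalId = animalId, group = group,
        samples = data.frame(
          t = seq(0, nSec, length.out = nFrames + 1L) * (params@durationS / nSec),
          x = c(0, cumsum(dx)),
          y = c(0, cumsum(dy))))
  })
}

#' Simulate a labelled cohort of trajectories
#'
#' Generates `nAnimals` trajectories per group specification, with
#' per-animal seeds derived deterministically from the cohort seed so the
#' whole cohort is reproducible from one integer.
#'
#' @param groupSpecs a list of specs, each a list with elements `group`
#'   (label), `params` (a [SimParams-class]; its own seed is overridden by
#'   the derived per-animal seed) and `nAnimals`.
#' @param seed cohort-level RNG seed.
#' @return a list of [WormTrajectory-class] objects.
#' @examples
#' coh <- simulateCohort(list(
#'   list(group = "sharp", params = sharpTurnParams(durationS = 30), nAnimals = 2),
#'   list(group = "shallow", params = shallowTurnParams(durationS = 30), nAnimals = 3)
#' ), seed = 99)
#' vapply(coh, groupLabel, character(1))
#' @export
simulateCohort <- function(groupSpecs, seed = 1L) {
  stopIfNot(is.list(groupSpecs) && length(groupSpecs) >= 1,
            "groupSpecs must be a non-empty list")
  for (sp in groupSpecs) {
    stopIfNot(all(c("group", "params", "nAnimals") %in% names(sp)),
              "each spec needs fields group, params, nAnimals")
    stopIfNot(sp$nAnimals >= 1, "nAnimals must be >= 1 in every group")
    stopIfNot(is(sp$params, "SimParams"), "params must be a SimParams object")
  }
  total <- sum(vapply(groupSpecs, function(sp) as.integer(sp$nAnimals), 1L))
  seeds <- deriveSeeds(seed, total)
  out <- vector("list", total)
  idx <- 0L
  for (sp in groupSpecs) {
    for (a in seq_len(sp$nAnimals)) {
      idx <- idx + 1L
      p <- sp$params
      p@seed <- seeds[idx]
      out[[idx]] <- simulateWormPath(
        p, animalId = sprintf("%s_%02d", sp$group, a), group = sp$group)
    }
  }
  out
}

#' Simulate step tables with a bimodal angle distribution
#'
#' Generates per-animal step tables directly (bypassing path geometry) with
#' inter-step angles drawn from a two-component Gaussian mixture and
#' lengths/speeds drawn independently of the mode. Used to probe the
#' step-symbolization stage against the 90-degree sharp/shallow rule on
#' data where the true class of every step is known.
#'
#' @param nAnimals number of animals.
#' @param stepsPerAnimal angle-bearing steps per animal.
#' @param angleMeans,angleSd means (degrees) of the sharp and shallow angle
#'   modes and common sd; draws are clamped to [0, 180].
#' @param pSharp probability a step comes from the sharp (first) mode.
#' @param seed integer RNG seed.
#' @return a list of [StepTable-class] objects (not yet normalized).
#' @examples
#' tabs <- simulateBimodalSteps(3, 50, seed = 5)
#' tabs[[1]]
#' @export
simulateBimodalSteps <- function(nAnimals, stepsPerAnimal,
                                 angleMeans = c(20, 160), angleSd = 12,
                                 pSharp = 0.5, seed = 1L) {
  stopIfNot(nAnimals >= 1 && stepsPerAnimal >= 1,
            "nAnimals and stepsPerAnimal must be >= 1")
  withLocalSeed(seed, {
    lapply(seq_len(nAnimals), function(a) {
      n <- stepsPerAnimal + 1L  # first step carries no angle
      sharp <- runif(stepsPerAnimal) < pSharp
      ang <- rnorm(stepsPerAnimal, ifelse(sharp, angleMeans[1], angleMeans[2]),
                   angleSd)
      ang <- pmin(180, pmax(0, ang))
      len <- pmax(1e-3, rnorm(n, 1.5, 0.5))
      spd <- pmax(1e-3, rnorm(n, 0.15, 0.05))
      tEnd <- cumsum(len / spd)
      new("StepTable", animalId = sprintf("bimodal_%02d", a), group = "bimodal",
          steps = data.frame(
            stepIdx = seq_len(n), tStart = c(0, tEnd[-n]), tEnd = tEnd,
            lengthMm = len, angleDeg = c(NA_real_, ang), speedMmS = spd,
            lengthNorm = NA_real_, angleNorm = NA_real_, speedNorm = NA_real_),
          normalized = FALSE, degenerateFeatures = character())
    })
  })
}
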