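---
title: "Run-length encoding path analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-length encoding path analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpath)
```

# The model

`wormpath` treats a 2-D centroid trajectory as a one-dimensional "texture":
the path is segmented into steps, each step is classified into a movement
pattern (sharp vs. shallow turn), and the resulting symbol string is
summarized by run-length statistics — the same family of statistics used to
quantify gray-level textures in images, transplanted to behavior. The
pipeline is a chain of small, individually testable stages.

## Step extraction

The track is linearly interpolated onto a regular grid of spacing
`deltaTs` (default **1 s**). The grid interval trades noise suppression
against fidelity: at 30 Hz raw sampling, 1 s averages out centroid jitter
while preserving the ~seconds timescale of turning behavior.

A **turning event** is declared at grid point *i* when the heading of the
displacement into *i* deviates by more than `thetaDeg` (default **40°**)
from the reference heading of the previous turning event. The first grid
point is always the initial event. Because an animal moving "straight"
still wobbles its heading by roughly ±30°, the 40° default sits just above
that band: straight runs are not fragmented, genuine reorientations are
caught.

Two conventions here were genuinely open and are worth stating:

* **Reference heading.** "The heading at the previous turning event" can
  mean the heading *into* or *out of* that event. We use the direction of
  the *first displacement leaving* the event, computed in one internal
  helper (`.postEventHeading`) so the alternative (incoming heading, or a
  segment-mean heading) can be swapped in one place. The outgoing
  convention has the attractive property that the scan can never re-trigger
  immediately after an event (the deviation at the next point is zero by
  construction).
* **Zero displacement.** A stationary interval has no heading; it inherits
  the previous one. A fully stationary track returns only the initial
  event, with a warning, rather than NaN propagation.

A **step** joins consecutive turning events; its length is the displacement
(mm), its speed length/elapsed time (mm/s), and its **angle** the interior
angle at its starting event between the vector back to the previous event
and the vector on to the next, in [0°, 180°]. The convention is chosen so
that 180° is straight continuation and 0° a full reversal; "sharp turn"
(< 90°) and "shallow turn" (≥ 90°) are then meaningful labels, and a
reversal is simply the extreme sharp turn — no separate reversal state
exists anywhere in the pipeline. The first step of each path has no
preceding step, hence no angle: it is kept for bookkeeping (path length,
elapsed time) but excluded from clustering and symbolization, whose
features would otherwise be incomplete.

Features are min-max normalized to [0, 1] **pooled across all animals of a
run**, not per animal: the step clustering is a single pooled fit, which
only makes sense on a common scale. A zero-range feature (possible in
degenerate synthetic data) maps to 0 and is flagged rather than producing
0/0.

## Symbolization

Normalized (length, angle, speed) triples of all angle-bearing steps are
clustered by `stats::kmeans` (Euclidean distance, `k = 2` by default,
2–5 supported, ≥ 10 restarts, 300 iteration cap, fixed seed). Raw k-means
labels are arbitrary, so clusters are relabeled to symbols by **ascending
mean raw angle**: symbol 1 is always the sharpest cluster. With k = 2 this
pins the semantics sharp/shallow regardless of initialization. Assignment
ties (exactly equidistant steps) go to the lowest symbol id; this is only
reachable on constructed data but is fixed for determinism.

On data with a bimodal angle distribution the two fitted symbols split the
angle axis close to 90°, and `angleRuleAgreement()` measures how closely
the fitted symbols match the plain 90° threshold rule — our stand-in
validation for the clustering granularity (a decision-tree re-validation of
k on the original laboratory data is out of scope here; it depends on data
we do not ship).

## Run-length matrices

The per-animal symbol string is compressed into maximal runs; `P(i, j)`
counts runs of symbol *i* with run length *j*. Four variants differ in the
column layout — IMF (individual maximum), AMF (cohort maximum, making
matrices comparable across animals with different track lengths), BAMF
(binned; column value = bin index) and BAAMF (binned; column value = the
animal's mean observed run length within the bin) — plus IMFL/AMFL, the
entrywise ln(1 + count) transforms of IMF/AMF. Binning uses singleton bins
{1},{2},{3} followed by dyadic spans [4,8],[9,16],[17,32],… doubling until
the cohort maximum, final bin truncated there; the doubling continuation is
the natural generalization of the printed 7-bin example (maximum 37), which
is exactly this scheme.

Numerical choices:

* **ln(1 + count)** rather than ln(count): these matrices are sparse and
  zeros must stay zeros.
* **Empty BAAMF bins** have no observed mean; they fall back to the bin
  midpoint and are flagged (`emptyBins`). Since the corresponding counts
  are zero, the fallback value never influences a descriptor; it only keeps
  the column-value vector well defined.
* **n_r is the total number of runs** (the standard run-length texture
  convention). Under this reading RP = n_r/n_p ∈ (0, 1] measures run
  homogeneity: 1 when every run has length 1.

## Descriptors and redundancy

Eleven descriptors summarize each matrix (formulas in `?computeDescriptors`
and the README): emphases weighted by powers of the run length j and the
symbol level i, the two nonuniformities ALN/RLN computed from squared
marginal sums, and RP. ALN/RLN use the squared *marginals*
((Σ_j P)², (Σ_i P)²) — the standard nonuniformity definitions, which is
also what "similarity of angle level / run length distributions" describes.
The implementation is vectorized; the test suite pins it against an
independent entry-by-entry loop oracle at 1e-12 relative tolerance, over
random strings with alphabets {1,2} and {1..5}.

Descriptors are strongly redundant, so before animal-level clustering a
**greedy Pearson filter** scans them in their canonical order (SRE, LRE,
LARE, HARE, SRLAE, SRHAE, LRLAE, LRHAE, ALN, RLN, RP) and keeps a
descriptor iff |r| < 0.9 against everything already kept. Greedy-in-fixed-
order is a deterministic choice among several defensible selection rules;
the kept set always satisfies the pairwise threshold by construction, which
is the property the tests assert. Zero-variance descriptors are dropped
with a warning. Which descriptors survive is data dependent; on our
synthetic cohorts typically 2–5 survive, mirroring the small reduced sets
seen on real data.

## Animal-level clustering

Kept (or all eleven) descriptors are min-max scaled over animals — they
span orders of magnitude (LRHAE in the tens, RP below 1), so unscaled
k-means would be dominated by one column — and clustered by k-means with
fixed seed and restarts. `compositionTable()` reports, per (group, cluster)
pair, the group's share of the cluster and the cluster's share of the
group; the two families sum to 1 within each cluster and each group
respectively, exactly. `stabilityReport()` reruns the clustering across
seeds and matrix kinds and reports the mean pairwise adjusted Rand index
(chance-corrected, label-permutation invariant); with real data unavailable
the cross-kind consistency of groupings is a reported score, not an
asserted one.

Default `kPath = 5` mirrors a five-condition experimental design (two
genotypes × food conditions plus one extra); the validation pipeline uses
`kPath = 2` on two simulated phenotypes.

# The synthetic generator

No quantitative generative model of worm locomotion is part of the method,
so the simulator is deliberately minimal: a discrete-time two-regime
process on a 1-second clock — aligned with the 1-second resampling grid, so
simulator statistics are directly interpretable in step units. Each second
the regime updates first (roam→turn with `pRoamToTurn`, turn→roam with
`pTurnToRoam`), then the heading updates under the new regime: Gaussian
jitter (`roamHeadingSdDeg`, default 10°, inside the ±30° straight-run band)
while roaming, a uniform reorientation of magnitude
[`turnAngleMinDeg`, `turnAngleMaxDeg`] with fair-coin sign each second
spent turning. Reversals are realized as turns near 180°, consistent with
the reversal-as-extreme-turn convention above. Within each second the
centroid advances frame by frame (default 30 Hz) with per-frame speeds
drawn from a Gaussian (default 0.15 ± 0.03 mm/s, a typical crawling speed)
truncated at zero — speeds are magnitudes.

Two presets define the study conditions used throughout the tests:
`sharpTurnParams()` (turns often: `pRoamToTurn = 0.45`, `pTurnToRoam =
0.5`, reorientations 100–180°, so step angles land mostly below 90°) and
`shallowTurnParams()` (turns rarely and gently: `pRoamToTurn = 0.08`,
`pTurnToRoam = 0.8`, 45–80°, so detected turns are mostly shallow). These
were calibrated once to produce the qualitative sharp/shallow dichotomy —
sharp-symbol fractions of roughly 0.6 versus well under 0.1 — that the
method is designed to detect; they emulate off-food-like searching versus
on-food-like dwelling.

What the simulator does **not** emulate: body posture (omega turns, head
bends), speed–turn coupling, spatial confinement (plate edges), food-patch
geometry, and tracking artifacts (centroid noise beyond what heading jitter
induces, dropped frames). Passing tests therefore demonstrate that the
pipeline recovers pattern-composition differences it was aimed at, on
clean tracks — not that it is robust to every artifact of real video
tracking.

# Problem sizes and determinism

Every stochastic component takes an explicit seed; cohort members and
pipeline stages get seeds derived deterministically from one master seed
(`sample.int` under a locally restored RNG state, so library code never
perturbs the caller's stream). Rerunning a configuration reproduces every
artifact byte for byte.

The shipped validation uses desk-scale problems chosen to exercise each
property comfortably: 60–120 s tracks for geometry and monotonicity
properties (100 random parameter draws for the Θ-monotonicity check),
1000 random strings (lengths 0–500) for the oracle and conservation
suites, and, for end-to-end phenotype recovery, 20 repetitions of a
40-animal, 300-second two-phenotype cohort run through the full pipeline
(BAMF matrix, correlation-filtered descriptors, k = 2), scoring the
fraction of animals in majority-pure clusters.

# Known limitations

* The Θ-monotonicity of turning-event counts is an empirical property of
  the reference-reset scan, verified over random synthetic paths, not a
  theorem; adversarial paths with headings straddling several thresholds
  could in principle violate it.
* With k > 2 the descriptor semantics of the angle-level weights (i²)
  inherit the symbol ordering by mean angle; LAE/HAE interpretations are
  documented for k = 2 and become ordinal beyond that.
* `selectDescriptors()` needs ≥ 3 animals and its outcome is
  data-dependent; on tiny cohorts the kept set can collapse to a single
  descriptor.
* BAAMF column values are per-animal; two animals' BAAMF descriptors are
  therefore computed on slightly different column grids by design (that is
  the point of the variant), which makes them less comparable across
  animals than BAMF's bin indices when bins are sparsely populated.
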