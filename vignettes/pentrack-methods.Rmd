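---
title: "PenTrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PenTrack: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PenTrack)
```

# The problem

Group-housed pigs spend most of the day lying, and shifts between lateral
lying, sternal lying, standing and walking are sensitive indicators of
welfare — heat, air quality and other stressors show up as changes in the
ethogram long before clinical signs. A ceiling camera plus a posture
detector yields, per frame, a set of bounding boxes each labelled
`standing_pig`, `sl_pig` (sternal lying) or `ll_pig` (lateral lying) with a
confidence. PenTrack takes it from there: it links those per-frame
detections into per-pig identities, turns the identities into activity
read-outs, and quantifies how well both the detector and the linker are
doing. The detector itself is out of scope by design — any model that can
emit labelled boxes (or a CSV of them) plugs in, and a built-in pen
simulator stands in for it so that the entire pipeline is testable with no
video, no trained weights and no animals.

All coordinates live in the 640x640 working frame (the standard detector
input size), origin at the top-left, x rightward, y downward, with the
continuous corner convention (width = `x_max - x_min`, no "+1"): boxes come
from resized, subpixel detections, not from integer pixel grids.

# Frame thinning by perceptual hash

Consecutive frames of a pen of resting pigs are nearly identical, and
annotating them all wastes effort while teaching a detector nothing. Each
frame is fingerprinted with a 64-bit perceptual hash: reduce to 32x32 by
bilinear interpolation, apply the orthonormal 2-D type-II DCT, keep the
top-left 8x8 low-frequency block, ravel it row-major into coefficients
$C_1 \dots C_{64}$, and set bit $i$ to 1 iff $C_i \ge m$ where $m$ is the
median of the 64 coefficients. Design points worth stating:

* The 32x32 pre-size is the canonical choice that makes the 8x8 block
  genuinely "low frequency"; it is a parameter (`size`) but there is no
  reason to change it.
* The DC coefficient is *included* in both the median and the bits — the
  hash is defined over all 64 selected coefficients. Ties ($C_i = m$) map
  to 1.
* Coefficients that are zero up to floating-point noise are snapped to
  zero (relative tolerance $10^{-10}$) before the median; without this a
  constant image would hash to rounding noise instead of the all-ones
  vector the transform dictates. The snap is relative, so the hash stays
  exactly invariant under positive intensity scaling.
* RGB input is collapsed by BT.601 luminance (0.299 R + 0.587 G +
  0.114 B).

`dedupStream()` walks a stream and keeps a frame only if its Hamming
distance to the *most recently kept* frame exceeds `maxDistance`
(default 1, i.e. only near-identical frames are dropped). Comparing to the
last kept frame rather than the immediate predecessor stops an arbitrarily
long run of 1-bit drifts from slipping through; the output is idempotent
under re-application.

# Tracking by detection

The linker is a classical SORT-family loop: predict, associate, update.

**State.** Each track carries an 8-dimensional Kalman state — box centre
$(c_x, c_y)$, aspect ratio $a = w/h$, height $h$, and their per-frame
velocities — under a constant-velocity model. Noise standard deviations
scale with box height (position-like terms $h/20$, velocity-like terms
$h/160$), so large (near) animals tolerate proportionally more jitter.
These are the conventional SORT/Deep-SORT magnitudes and are exposed as
`posWeight`/`velWeight` in `trackerParam()`.

**Association.** Cost between a track's predicted box and a detection is
$1 - \mathrm{IoU}$; the global minimum-cost assignment is found by an
$O(n^3)$ shortest-augmenting-path Hungarian solver (`solveAssignment()`),
and any assigned pair with IoU below `iouGate` (default 0.3) is severed
afterwards. The gate keeps a cheap global optimum from forcing a
geometrically absurd match. Appearance information — in the original
systems a learned re-identification embedding — enters through a hook: any
function `(track, detection) -> cost in [0, 1]` can be blended via
`appearanceWeight`. The default is pure IoU/motion cost, which at pen
scale (a handful of well-separated animals) is sufficient; the hook exists
because coat markings or embeddings are the natural next step and should
not require touching the loop.

**Lifecycle.** Matched tracks take a measurement update, adopt the
detection's posture label, and reset their missing-frame counter.
Unmatched tracks coast on prediction, and retire once they have been
missing for more than `maxAge` frames — 50 by default, i.e. 10 s at 5 FPS,
so a pig occluded by the feeder for up to 50 frames keeps its identity and
a longer disappearance yields a fresh id (exactly one identity switch as
the evaluator counts it). Tracks are confirmed on first detection with no
probation period: the group size is small and fixed, and false positives
are cheap to recognise in evaluation rather than suppress in tracking.
Unmatched detections spawn new tracks with fresh ids, assigned in raster
order for determinism.

**Clips.** Footage is processed as 1-minute clips at 5 FPS (300 frames).
First-frame pigs receive ids 1..k in raster order — sorted by `y_min`,
then `x_min`. The original system assigned first-frame ids "based on the
hierarchy of the detected pigs", which is underspecified; raster order is
this package's deterministic reading, and is a labelling convention only.
Id counters reset per clip; stitching identities across clips (done
manually by coat markings in the original study) is out of scope.

# Activity scoring

**Walking.** A standing pig whose centroid moves more than
`walkThreshold` pixels between consecutive frames is walking. The default
threshold is 4 px. The source convention does not state whether those
pixels are in the native 1920x1080 frame or the resized 640x640 one; this
package applies it in the working (resized) frame and exposes the
parameter, which is the honest rendering of an underdetermined rule. The
rule never fires for lying pigs: box jitter on a resting animal is not
locomotion.

**Distance and speed.** Per-track total distance sums the centroid
displacements of walking pairs only. Summing *all* displacements would
count detector jitter as distance; since the rule for "is moving" exists,
the distance budget uses it, and the unfiltered sum is still reported as
`raw_displacement` for comparison. Headline speed divides total distance
by time actually spent walking (`speed_walking`); distance over the
clip's wall-clock span is also emitted (`speed_overall`), since "time
taken" admits both readings.

**Posture scores.** The individual score is
$P_i(a) = \sum_{k=1}^{n} AF_k / n$: the fraction of the clip's $n$ frames
in which pig $i$ shows activity $a$. Frames where the pig is undetected
contribute zero to the numerator but stay in the denominator — occlusion
depresses scores rather than silently renormalising them, which is also
why group scores from a pen with a large feeder run high-variance. The
group score is the average per-frame count of pigs in activity $a$ (range
0 to group size), and equals the sum of individual scores by exchange of
summation order. Walking is scored as a fourth activity overlapping
standing, not as a partition member.

**Phases.** `phaseAggregate()` summarises per-hour scores across
replicate days for each (session, phase, activity) cell — phases being
the hours before, during and after a treatment such as a ventilation
closure. Cells with a single replicate report sd 0 with an
`insufficient_replicates` flag rather than being dropped; absent cells are
absent, never imputed.

# Evaluation

**Detection.** `averagePrecision()` is Pascal-VOC style: detections of a
class ranked by descending confidence (ties broken deterministically by
frame then position), matched greedily to the same-frame ground-truth box
of highest IoU, each ground-truth box consumable once; a detection below
the IoU threshold, or hitting a consumed box, is a false positive. AP is
the all-point-interpolated area under precision-recall (the VOC-2010+
convention, not the 11-point variant), and mAP the unweighted class mean.
The default IoU threshold is 0.5, the threshold at which headline mAP
values are customarily reported; 0.6 — the stricter localization
criterion used in the source study — is a parameter away.

**Tracking.** `evaluateMot()` implements CLEAR-MOT accounting:
$$\mathrm{MOTA} = 1 - \frac{\sum_i (FN_i + FP_i + IDSW_i)}{\sum_i GT_i},
\qquad
\mathrm{MOTP} = \frac{\sum_{t,i} d_i^t}{\sum_i c_i},$$
with matching *persistence*: a ground-truth object keeps its previous
hypothesis while their IoU stays above threshold, only the remainder
enters the per-frame Hungarian step, and an identity switch is counted
when a matched object's hypothesis id differs from the last id it ever
carried. The match-quality distance $d$ is IoU (higher is better), the
natural companion to IoU-based localization; a centre-distance variant
(`metric = "center"`, lower is better) is provided. MOTA is bounded above
by 1 and can go negative under a false-positive flood — that is a feature
of the metric, and is tested.

# The pen simulator

`simulatePen()` generates the ground truth that real barn video would
otherwise provide: `nAnimals` pigs (default 5, a typical experimental
group) in a 640x640 arena at 5 FPS. Postures evolve as a per-frame Markov
chain over the three classes; the default transition matrix is sticky
(diagonal 0.97–0.98), with stationary distribution of roughly 18%
standing, 36% sternal and 46% lateral — lying dominates, as it does in
housed fattening pigs. Standing pigs take heading-persistent random-walk
steps (step length |N(3, 1)| px/frame, heading diffusion 0.5 rad,
reflection at the walls); lying pigs are stationary. Boxes are sized by
posture — lateral lying widest (120x72), then sternal (100x56), then the
standing footprint (80x40) — an invented but necessary convention, since
IoU-based tests are vacuous when all boxes coincide. A feeder rectangle
covering ~15% of the arena hides any pig whose centre enters it,
reproducing the blind spot a large feeder casts in a real pen; initial
postures come from the chain's stationary distribution and initial
positions from a jittered grid. Everything derives from one integer seed
and is bit-reproducible.

Ground-truth walking distance is *defined* by the same supra-threshold
rule the activity module applies. This is deliberate: it makes walking
recovery a sharp equality rather than an approximate one, at the cost of
not testing the rule itself against an independent notion of walking (no
such notion exists without kinematic ground truth).

`emitDetections()` is the detector stand-in: independent per-detection
misses, Gaussian box jitter, Poisson false positives and label flips, all
seeded. `renderFrame()` draws the pen as a grayscale matrix (ellipses in
boxes, dark feeder) to feed the hash pipeline.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: correlated detector failures (huddled pigs
missed together), systematic box bias, posture-dependent miss rates,
lighting and motion blur, pigs entering or leaving the pen, and any
dose-response of behaviour to air quality (scenario differences are the
user's job, via per-phase transition matrices). Recovery results on the
simulator certify the plumbing, not the detector.

# Numerical choices and test scales

* `floor(ratio * N)` training size with a $10^{-9}$ epsilon before the
  floor, so exactly-representable products (0.9 x 6680 = 6012) are not
  pushed down a unit by binary floating point.
* Hungarian costs must be finite; degenerate (zero-area) boxes are a
  domain error everywhere, not a silent 0.
* Kalman covariance is re-symmetrised after each update; predicted boxes
  of long-coasting tracks are clamped away from degeneracy before IoU.
* Score/evaluation ties (equal confidences, equal IoUs) are broken
  deterministically (frame, then position; first index in the solver).
* Verification scales: clip-level scenarios use 5 pigs x 300 frames;
  stochastic recovery uses 20 noise seeds over 200-frame clips with a
  3-binomial-sd band; the chain-occupancy check runs one pig for 50,000
  frames against the analytic stationary eigenvector with a
  mixing-time-inflated band. These sizes give the properties sharp
  expected values while keeping the default suite near a minute.

# Limitations

Identities do not persist across clips; pixel distances are not converted
to metres (no camera calibration is modelled); no statistical testing of
behaviour differences between phases is provided (the read-outs are
descriptive means and sds); rotated or elliptical boxes are not supported;
and the tracker's appearance hook is a contract, not an implementation —
a learned re-identification model is explicitly out of scope.
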