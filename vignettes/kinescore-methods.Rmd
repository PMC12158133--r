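---
title: "kinescore methods: from 2D keypoints to mobility scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinescore methods: from 2D keypoints to mobility scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinescore)
```

# The model

`kinescore` treats camera-based physiotherapy assessment as three successive
abstractions over a stream of 2D skeletons:

* **Layer 1 — observations.** Per frame: 17 named keypoints in the COCO
  order, each `(x, y, visibility)` normalized to the image (origin top-left,
  y downward), a person bounding box `(cx, cy, w, h)`, and a millisecond
  timestamp. Visibility follows the 0/1/2 convention; a keypoint with
  visibility 0 is ignored by every downstream computation. Timestamps are
  strictly increasing integers.
* **Layer 2 — kinematics.** Segment and joint angles for 17 mobility
  parameters, their time derivatives, the time spent inside predefined
  angular ranges, and postural sway. Which parameters are computable depends
  on the subject's gross orientation toward the camera, so orientation
  classification precedes angle computation.
* **Layer 3 — scores.** A 0–75 score per parameter driven by the achieved
  range of motion, a traffic-light summary of range coverage, normalized
  body-part and global scores, and structured sub-reports for standardized
  clinical scales.

All internal geometry converts the y-down image frame to a y-up mathematical
frame at the point where angles are computed, so angle conventions stay
conventional while the I/O layer matches the pose-format ecosystem.

# Angle constructions

Pose formats name landmarks, not angles, so each parameter needs an explicit
construction. These are the package's own conventions, chosen so that every
parameter is an exact inverse of the synthetic generator's forward kinematics
in the view it is assessed in (see *Synthetic data* below); each is
deliberately simple enough to audit:

| Code(s) | Construction |
|---|---|
| LHTL / LHTR | Signed angle between the inter-ear line (fallback: inter-eye) and the inter-shoulder line; positive feeds the left code, the magnitude of negative values the right code. Measuring against the shoulder line rather than the image horizontal makes the tilt trunk-relative. |
| HRL / HRR | `atan(2 (nose_x − midear_x) / (interear · cos τ))` where τ is the lateral tilt estimate. For a head modeled as a circle of radius e (half the inter-ear distance) with the nose on the circle, the projected nose offset is `e sin ρ cos τ` and the projected inter-ear distance `2 e cos ρ`, so the arctangent of their (tilt-corrected) ratio recovers the rotation ρ exactly. An arcsine of the uncorrected ratio — the more obvious guess — is *not* the inverse of this geometry (the ratio is `tan ρ`, not `sin ρ`) and is wrong by >5° at ρ = 30°. |
| FHT | Profile view: angle of the mid-ear → nose vector against the horizontal, minus the trunk inclination, so only head-on-trunk pitch remains; magnitude stored (the code does not distinguish forward from backward). |
| WSAL / WSAR | Angle at the shoulder between the shoulder → wrist vector and the downward trunk axis (mid-shoulder → mid-hip); per side, 0–180°. |
| AELL / AELR | The wrist–shoulder angle capped at 90°, accepted only when the elbow is within 15° of the shoulder–wrist line ("extended arm"); bent-elbow samples are dropped rather than scored. |
| HAAL / HAAR, LELI / LELR | Angle of the hip → ankle vector against the downward vertical, per side, capped at 90°. |
| LTTL / LTTR | Signed angle of the mid-hip → mid-shoulder axis from vertical, lateral direction; sign-split into the two codes. |
| FTIF / FTIB | Profile view: the same trunk axis, signed in the sagittal direction. The facing direction (nose leading the mid-shoulder point) disambiguates forward from backward. |

Sign-split codes (LHT, HR, LTT, FTI) are total: at every sampled instant the
active side's code records the magnitude and the opposite code records 0, so
scoring never sees gaps. Per-side codes (WSA, AEL, HAA, LEL) sample whenever
their own side's keypoints are visible.

**Orientation gating.** Frontal (and Turned) views enable the frontal-plane
codes — everything except FHT, FTIF, FTIB; Profile enables those three plus
the wrist–shoulder and hip–ankle angles. Turned results are flagged
`confidence = "low"` rather than reweighted: there is no principled
confidence model for oblique views, so the package flags and lets the
consumer decide. Gated-out codes return `valid = FALSE`, score 0, and are
annotated "not assessed" so denominators stay fixed (a config flag
`renormalize_gated` instead renormalizes by the assessable codes).

# Kinematics

* **Derivatives.** Angular velocity uses central finite differences on
  interior samples and one-sided differences at the ends (deg/s);
  acceleration applies the same operator to the velocity series. No
  smoothing is applied by default; `smoothing_ms` enables a centered moving
  average for noisy detector output.
* **Time in range.** Ranges are half-open `[lo, hi)` with the last range
  closed, so every angle belongs to exactly one range and a boundary angle
  (30°) belongs to the upper range. Each inter-sample interval is assigned
  to the range of its left sample; durations therefore sum exactly to the
  trace duration.
* **Postural sway.** Per consecutive window of `window_ms`: the RMS
  Euclidean deviation of the mid-hip point from its window mean, in
  normalized image units. A window longer than the sequence degrades to a
  single whole-sequence window with a warning.

# Scoring

The running score is driven by the maximum angle achieved so far,
`P_i(t) = 25 k + 25 (θ_max − lo_k)/(hi_k − lo_k)` for θ_max in range k. Two
genuinely open choices were resolved as follows:

* **Within-band mapping.** The score bands are printed as intervals
  ([0–25], [25–50], [50–75]) without an interpolation rule. A continuous
  piecewise-linear mapping on the maximum angle was chosen over band-constant
  scores so that progress *within* a band is visible between sessions;
  `band_constant_scores = TRUE` restores the step mapping (band upper bound).
* **Dwell time.** Time-in-range is computed and reported alongside the
  score but does not enter P_i: the score bands are defined by range reached
  alone, and folding dwell time in would make the score depend on exercise
  duration.

The traffic light counts distinct ranges the *instantaneous* angle occupied:
three → green, two → orange, one (or none) → red; precedence green > orange
> red resolves the overlap in the prose definitions ("moved through more than
one range" includes "all ranges").

**Denominators.** Head 375 (5 × 75) and Arms/Legs/Torso 300 (4 × 75) follow
from the parameter counts. The printed whole-body denominator of 1575 is
arithmetically inconsistent with 17 parameters × 75 = 1275 — and the four
part denominators themselves sum to 1275 — so the package defaults to 1275
and leaves 1575 selectable (`body_denominator`) rather than guessing intent.
With the default, the global numerator equals the sum of the part numerators
exactly.

**Clinical-scale mapping.** The eight supported scales receive structured
sub-reports: contributing parameter codes, the kinematic quantities the
pipeline can actually supply, dimension coverage flags
(strength/stability/mobility/pain/coordination), and the aggregate of the
contributing normalized scores. Inputs the pipeline cannot provide (facial
pain expressions for the Ashworth and stroke scales, gait-phase timing for
ambulation classification) are listed as missing, never imputed, and no
scale-point totals (e.g. a Berg 0–56 score) are fabricated: the mapping
identifies what informs each scale, it does not define a conversion.

# Orientation classification

Features are the 12 numbers a foreshortening cue lives in: left/right
shoulder and hip positions plus the bounding box. The pipeline is the
standard one — stratified 80/20 split under a fixed seed, per-feature
standardization with *training-set* statistics (population standard
deviation, so the transformed training set has exactly unit variance;
constant features are dropped with a warning), six classifiers compared by
test accuracy, best one selected. Ties resolve toward the canonical order
LR, DT, RF, NB, KNN, SVM, which also encodes the preference for the most
interpretable model among equals. Scale-sensitive algorithms (LR, KNN, SVM)
receive standardized features; trees and naive Bayes see raw features. PCA
to three components is implemented but off by default: on these features it
discards the foreshortening signal and measurably hurts accuracy.
Stratification is an addition to the plain random split: with small test
sets an unstratified split makes per-class accuracy estimates unstable.

Four of the six classifiers (CART decision tree, bagged random forest,
Gaussian naive Bayes, RBF-kernel C-SVM with the dual solved exactly by
quadratic programming) are implemented inside the package at their
conventional defaults (Gini splits grown to purity; 100 trees with
√p features per split; variance smoothing 1e-9; C = 1, γ = 1/(p·Var X),
one-vs-one voting) because no implementation exists in the dependency set;
logistic regression and k-NN delegate to `glmnet` and `FNN`. Each has its
own unit tests against hand-computed oracles.

Sequence-level orientation is a majority vote over per-frame predictions;
the per-frame classifier is deliberately stateless.

# Synthetic data

The generator emulates a single standing adult viewed by a fixed camera:
an articulated skeleton with anthropometric default proportions (biacromial
half-width 0.115 of image height, bi-iliac 0.08, trunk 0.25, arm 0.28, leg
0.40), forward kinematics for head/arm/leg/trunk angles, orthographic
projection (mediolateral offsets scale by cos yaw; depth is discarded), and
isotropic Gaussian keypoint jitter with sd 0.01 of image width — a
realistic magnitude for pose-detector noise at this figure scale. Frames
default to 25 fps (40 ms), consumer-video rate. The head is a horizontal
circle of radius half the inter-ear distance with the nose on the circle,
which is what makes the rotation estimator above exact.

Orientation classes are defined by yaw bands Frontal [0°, 15°], Turned
[25°, 60°], Profile [70°, 90°], mirrored left/right by a fair coin. The
deliberate gaps (15–25°, 60–70°) make the labels well-defined: there is no
operational boundary for "turned" in common use, and placing samples inside
an arbitrary boundary would only encode label noise. The bands are
configurable.

Orthographic rather than perspective projection is sufficient to create the
foreshortening cue the classifier needs; perspective would add camera
parameters with no benefit at this abstraction level. What the generator
does **not** emulate: occlusion and missing detections, detector noise that
correlates across joints or over time, clothing/body-shape variation,
multiple people, and perspective distortion. A green test suite therefore
establishes the internal consistency of the pipeline — angles invert the
kinematics, scores follow the stated mapping, the classifier separates the
stated world — not clinical validity on real patients, which requires real
annotated recordings.

# Numerical choices and degenerate inputs

* Angles are computed with `atan2`/`acos` on clamped cosines; coincident
  points are errors, not NaNs.
* Range partitions are validated (contiguous, covering the span) before use;
  out-of-span angles are clamped with a warning.
* Trace timestamps are integer milliseconds; duplicate timestamps are
  rejected at sequence construction with the offending indices named.
* Traces too short for a derivative return an empty series with a warning
  rather than erroring, so batch pipelines keep moving.
* All stochastic fits consume the R random stream and are bit-reproducible
  under `set.seed`; the generator returns bit-identical output for identical
  (seed, spec) pairs.
* Report updates are append-only with strictly increasing timestamps across
  batches; finalizing freezes scores and any later update is an error.
  Streaming and single-shot processing produce byte-identical rendered
  reports because scoring is recomputed from the accumulated samples.

# Known limitations

* Angle constructions are conventions; other constructions (e.g. elbow-apex
  wrist–shoulder angles) are defensible and would score differently.
* The head-rotation estimate degrades away from the frontal view and with
  large simultaneous head pitch; it is exact only for the circular-head
  model it inverts.
* In profile view the two body sides project onto each other; per-side codes
  are still computed but cannot be attributed reliably — a detector with
  left/right confusion will corrupt them.
* Turned-view angles are flagged, not corrected; no 3D lifting is attempted.
* The sway metric is a position-dispersion summary, not a validated balance
  score.
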