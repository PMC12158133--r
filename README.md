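# kinescore

Camera-based physiotherapy assessment from 2D skeletal keypoints.

Markerless pose estimators (YOLO-pose, OpenPose, MediaPipe, ...) emit per-frame
skeletons — 17 COCO-layout landmarks plus a person bounding box — but a
physiotherapist reasons in clinical terms: ranges of motion, postural
stability, standardized scale scores. `kinescore` bridges that gap with a
three-stage pipeline for anyone building or evaluating vision-based
rehabilitation tools:

1. **Pose I/O** — read/write YOLO-pose text records (56 normalized tokens per
   person), convert CVAT per-segment annotations into single-person records,
   and assemble validated, millisecond-timestamped motion sequences.
2. **Kinematics (layer 2)** — classify the subject's gross orientation
   (Frontal / Turned / Profile) from shoulder, hip and bounding-box features
   with a compared-and-selected classifier, then compute 17 angle parameters
   (head tilt/rotation, wrist–shoulder angle, arm/leg lateral elevation,
   hip–ankle angle, trunk tilt/inclination), their angular velocity and
   acceleration, time spent in predefined angular ranges, and postural sway.
3. **Scoring (layer 3)** — map each parameter's achieved range of motion onto
   a 0–75 score, summarize range coverage as a green/orange/red traffic light,
   normalize per body part and globally, and emit structured sub-reports for
   eight standardized clinical scales (Motor Index, Modified Ashworth, Berg
   Balance, FAC, Catherine Bergego, Barthel, Lawton–Brody, DRS, NIHSS).

A synthetic articulated-skeleton generator with exact ground-truth angles and
orientation labels makes every stage testable without video or a trained pose
network.

## The scoring model

Each parameter *i* analyzes an angular span split into three ranges (head,
leg, torso parameters and arm lateral elevation: 0–30°, 30–60°, 60–90°;
wrist–shoulder angle: 0–60°, 60–120°, 120–180°) mapped onto the score bands
[0–25], [25–50], [50–75]. The running score is driven by the maximum angle
achieved so far: with θ<sub>max</sub>(t) in range *k* (0-based, bounds
[lo<sub>k</sub>, hi<sub>k</sub>)),

    P_i(t) = 25·k + 25·(θ_max(t) − lo_k) / (hi_k − lo_k)   ∈ [0, 75]

so P<sub>i</sub> is continuous, non-decreasing, and the final evaluation is
the last updated score. Range coverage gives the traffic light (all three
ranges → green, two → orange, one → red). Normalized scores divide summed
P<sub>i</sub> by the part maxima — Head Σ<sub>i</sub>P<sub>i</sub>/375,
Arms/Legs/Torso /300, whole body /1275 by default (see the methods vignette
for the denominator discussion).

## Worked example

Train an orientation model on synthetic data, simulate a scored exercise
session, and render the report:

```r
library(kinescore)

ds    <- generate_orientation_dataset(600, config = default_config(), seed = 1)
X     <- orientation_feature_matrix(ds$frames)
split <- split_dataset(ds$labels, seed = 1)
model <- train_and_compare(X, ds$labels, split, seed = 1)
model
#> <classifier_report>
#>   LR   accuracy 0.9500  <- selected
#>   DT   accuracy 0.9250
#>   RF   accuracy 0.9250
#>   NB   accuracy 0.9417
#>   KNN  accuracy 0.9000
#>   SVM  accuracy 0.9500

spec <- trajectory_spec(
  list(head_tilt_deg          = rbind(c(0, 0), c(4000, 70)),
       arm_abduction_left_deg = rbind(c(0, 0), c(4000, 130)),
       arm_abduction_right_deg = rbind(c(0, 0), c(4000, 45))),
  duration_ms = 4000, fps = 25
)
session <- generate_sequence(spec, noise_sd = 0.005, seed = 2)
orient  <- sequence_orientation(model, session$sequence)   # "Frontal"
report  <- finalize_report(update_report(mobility_report(orient), session$sequence))
cat(render_report(report, "text"), sep = "\n")
```

The report lists one line per parameter; excerpt:

```
code         Pi traffic  ranges
LHTL      58.49 [GREEN]  0,1,2
LHTR       0.28 [RED]    0
WSAL      54.05 [GREEN]  0,1,2
AELL      75.00 [GREEN]  0,1,2
AELR      37.60 [ORANGE] 0,1
FHT        0.00 [RED]            not assessed

Part scores:
  Head   0.276
  Arms   0.618
  Legs   0.029
  Torso  0.015
Global score: 0.237
```

Reading it: the simulated subject tilted the head 70° to the left, so `LHTL`
traversed all three ranges (green) and scored 25·1 + 25·(70−60)/30 ≈ 58.3
(plus keypoint noise); the right-side code `LHTR` stayed red near 0. The left
arm rose through 130° (`WSAL` green, `AELL` capped at its 90° span → 75), the
right arm reached only 45° (orange). Sagittal codes (`FHT`, `FTIF`, `FTIB`)
are not assessable in a frontal view and score 0, flagged. Part scores are
the summed P<sub>i</sub> over the part's codes divided by the part maximum;
the clinical-scale section (not shown) lists, per scale, the contributing
codes, the quantities available, and any inputs the pipeline cannot provide
(e.g. facial pain expressions).

## Command line

```sh
inst/cli/kinescore simulate --spec spec.yaml --seed 3 --out seq.ndjson --truth truth.csv
inst/cli/kinescore train-orientation --data set.ndjson --labels labels.csv --seed 42 \
    --out model.rds --report table.json
inst/cli/kinescore analyze --input seq.ndjson --orientation Frontal --out layer2.json
inst/cli/kinescore run --input seq.ndjson --model model.rds --out report.json --text
```

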