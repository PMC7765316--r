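---
title: "From inertial sensors to trajectory heatmaps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From inertial sensors to trajectory heatmaps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajheat)
```

## The problem

Human activity recognition (HAR) from body-worn inertial measurement units
(IMUs) usually classifies raw acceleration/orientation time series directly.
An alternative is to move the problem into the image domain: reconstruct the
3D trajectories of a few body points, flatten each windowed trajectory to a
2D plane, and rasterize it into a *crossing-count heatmap* — an image whose
pixel values count how often the trajectory crossed that pixel within the
window. Image classifiers (and image data augmentation) then apply directly,
and the images themselves are interpretable: an arm circle looks like a
ring, a squat like an arc.

`trajheat` implements this pipeline end to end for a six-sensor setup
(wrists, knees, head, lower back) sampled at 60 Hz:

1. **Calibration / root normalization** of raw IMU readings,
2. a **dead-reckoning drift diagnostic** showing why naive double
   integration cannot produce trajectories,
3. **windowing and PCA flattening** of 3D vertex trajectories,
4. **rasterization** into count heatmaps and assembly of image-sequence
   tensors,
5. **augmentation** by exact flips/quarter-turns,
6. three **classifiers** (raw-signal LSTM, 1-D ConvLSTM, image ConvLSTM),
7. **leave-one-person-out (LOPO) evaluation** with confidence intervals,
   confusion matrices and a cohort-size sweep.

Trajectory *estimation from real IMUs* requires an external full-body pose
model and is out of scope; instead a seeded synthetic motion simulator
generates labeled vertex trajectories (and physically consistent synthetic
IMU streams), so every stage is testable at desk scale.

## Sensor model and calibration

A sensor reports acceleration $a_{\mathrm{IMU}}(t)$ in its own frame and an
orientation matrix $R_{\mathrm{IMU}}(t)$ (sensor → global). Vectors are
columns; rotations act by left multiplication. Gravity is fixed at
$g = (0, 0, -9.81)^\top$ m/s² in a right-handed, z-up global frame.
Calibration removes gravity and expresses readings in a body-fixed
convention:

$$a_{\mathrm{noG}} = R_{\mathrm{IMU}} a_{\mathrm{IMU}} - g,\qquad
  a_{\mathrm{local}} = R_{\mathrm{calib}}\, a_{\mathrm{noG}},\qquad
  R_{\mathrm{local}} = R_{\mathrm{calib}} R_{\mathrm{IMU}} R_{\mathrm{bone}}.$$

$R_{\mathrm{calib}}$ and $R_{\mathrm{bone}}$ come from a known static
calibration pose; the package accepts them as inputs and provides the
synthetic convention `calibration_from_pose()`:
$R_{\mathrm{calib}} = R_{\mathrm{IMU}}(t_{\mathrm{calib}})^{-1}$,
$R_{\mathrm{bone}} = I$. Every reading is then normalized to the pelvis
(lower-back) sensor as the body root:

$$a_{\mathrm{norm}} = R_{\mathrm{root}}^{-1}(a_{\mathrm{local}} -
  a_{\mathrm{root}}),\qquad
  R_{\mathrm{norm}} = R_{\mathrm{root}}^{-1} R_{\mathrm{local}}.$$

$R_{\mathrm{root}}^{-1}$ is taken as the transpose; orthonormality (and
$\det = +1$) is validated on input at $10^{-8}$. Root normalization makes
the root channel trivial ($a = 0$, $R = I$), which is why the raw-signal
feature matrix has $5 \times (3 + 9) = 60$ columns for six sensors: five
non-root sensors, each contributing its normalized acceleration and the
nine entries of its normalized orientation. A 5 s window at 60 Hz is then
the familiar 300 × 60 input.

Gravity carries no time index: it is treated as a constant of the global
frame, not re-estimated per frame.

### Why dead reckoning is only a diagnostic

Double integration of acceleration with the semi-implicit update
$v_{t+\Delta t} = v_t + \Delta t\, a_{t+\Delta t}$,
$x_{t+\Delta t} = x_t + \Delta t\, v_{t+\Delta t}$
(`dead_reckon()`) turns a constant sensor bias into a linear velocity error
and a quadratic position error: the log–log slope of error versus elapsed
time is 2 (`drift_loglog_slope()`), so position drifts without bound. Two
numerical notes:

* The update is implemented exactly as the recurrence above (acceleration
  evaluated at the *end* of the step). It is a first-order integrator:
  round-tripping a synthetic IMU stream back through `dead_reckon()`
  recovers the trajectory with an error that shrinks *linearly* as the
  sampling interval shrinks (the tests assert a ≥ 1.7× error reduction per
  halving of $\Delta t$, plus the quadratic-in-time drift law). A
  higher-order scheme would recover quadratically but would not be the same
  recurrence.
* The synthetic IMU inverts this construction: acceleration is the second
  central finite difference of position, expressed in the sensor frame with
  gravity added back, so calibration followed by integration is an exact
  inverse up to discretization.

## Windows, PCA flattening and heatmaps

Trajectories are cut into non-overlapping fixed-length windows (default
stride = window length; strides up to the window length are allowed for
overlap). Defaults follow the classifier input sizes: 150 frames (2.5 s)
per heatmap sub-window, 300 frames (5 s) for raw-signal models.

Each window of one vertex is flattened from 3D to 2D with PCA
(`pca_project()`): center, project onto the top two eigenvectors of the
sample covariance. Body-point motion is nearly planar but the plane's
orientation is arbitrary; PCA recovers the in-plane shape regardless of
subject heading. Choices that matter:

* **Per-window, per-vertex fit** (default). Each body part's motion gets
  its own maximally spread plane. A `shared_basis` flag pools all vertices
  of a window instead, and `project_per_subwindow = FALSE` shares one basis
  per vertex across a whole segment, for users who want cross-channel or
  cross-time comparability.
* **Deterministic sign**: each axis is flipped so its largest-magnitude
  loading is positive (ties toward the first coordinate). Eigenvector sign
  is otherwise arbitrary and would break bit-reproducibility.
* **Degenerate windows** (all points identical) are kept, flagged
  `constant`, and rasterize to a single pixel — stationary segments are
  legitimate data, not errors.

`rasterize()` maps a window's 2D points onto an `H × W` grid: the window's
bounding box, padded by 5%, is scaled *isotropically* (one scale for both
axes, centered) so motion shape is preserved rather than stretched; pixel
$(r, c)$ covers the half-open box $[r, r+1) \times [c, c+1)$ and the
maximum coordinate falls into the last pixel. In the default `segments`
mode every pixel crossed by each straight segment between consecutive
points is incremented once per segment (an exact grid walk, implemented in
C++); a `points` mode bins sample points instead, conserving the point
count exactly. Because windows are mapped symmetrically, segments between
window extremes pass *exactly* through pixel corners; passes within
$10^{-9}$ (in segment parameter) of a corner are treated as corner
crossings that enter only the diagonal neighbor, so rasterization is
deterministic and matches an independent crossing-enumeration oracle
pixel-for-pixel. Grids are normalized to $[0, 1]$ by their maximum
(all-zero grids pass through unchanged).

`build_image_sample()` assembles the classifier input: a 600-frame segment
splits into 4 sub-windows of 150 frames; each of the 6 vertex channels is
PCA-flattened and rasterized per sub-window, giving a
4 × 6 × 64 × 64 tensor by default.

## Augmentation

Training sets are enlarged with *exact* label-preserving pixel
permutations: horizontal/vertical flips and quarter-turn rotations
(`augment_ops()`). Arbitrary-angle rotations are deliberately excluded —
they interpolate and break the count semantics of the grids. Augmentation
acts in image space after heatmap generation, originals are always kept,
op draws are seeded, and augmented samples carry a provenance flag; the
evaluator asserts that no augmented sample ever reaches a validation or
test fold. Flips are applied globally; for direction-sensitive activity
pairs (cross vs. side stepping) a per-class policy can be configured
instead.

## Classifiers

Three architectures (`model_config()`, `build_model()`), all ending in a
dense softmax over the activity classes and trained with Adam on the
categorical cross-entropy
$L = -\log\!\big(e^{s_p} / \sum_j e^{s_j}\big)$
(evaluated with log-sum-exp; with all scores equal over $C$ classes,
$L = \ln C$):

* `lstm_raw` — two stacked LSTM layers (100 units each) over the 300 × 60
  normalized signal, a 100-unit dense interpretation layer, softmax.
* `convlstm_image` — two convolutional-LSTM layers (16 filters 5 × 5, then
  32 filters 3 × 3, 'same' padding), each followed by 2 × 2 spatial
  max-pooling, over the heatmap image sequence; then time-distributed
  flattening and a shared 100-unit dense layer, concatenation over the 4
  time steps, softmax. Pooling is spatial only; the recurrent state is
  stateless across samples and runs over the sub-window axis. The input
  layout is (time, channel = vertex, height, width).
* `convlstm_1d` — the same recurrent-convolutional topology with 1-D
  kernels over the 60-feature axis of the raw signal (one step per frame);
  the final hidden state provides the features (with 300 steps,
  time-distributed flattening would be needlessly wide).

The layers are implemented in-package on BLAS matrix products (im2col
convolutions, full backpropagation through time, Adam with bias
correction); analytic gradients are verified against finite differences in
the test suite. Initialization is seeded Glorot-uniform with forget-gate
biases at 1. Hyperparameters the architecture sketch leaves open are fixed
at conventional defaults, all overridable: 100-unit layers, learning rate
$10^{-3}$, batch 32, up to 100 epochs, early-stopping patience 10.
Early stopping watches validation loss and restores the best-validation
weights. Prediction is arg-max probability with ties broken toward the
lowest class index; batch composition does not affect results.

## Evaluation protocol

`evaluate_lopo()` runs leave-one-person-out cross-validation: one fold per
subject (sorted IDs), that subject tests, the rest train. One training
subject, drawn with a seeded generator, is held out as the early-stopping
validation set; with only one training subject (2-subject cohorts) a
seeded quarter of its samples is held out instead. Accuracy is computed
per window sample. The report carries per-fold accuracies, their mean, a
95% half-width $1.96\,\mathrm{sd}/\sqrt{n_{\mathrm{folds}}}$ (the "±"
convention; undefined below 2 folds), and a row-normalized confusion
matrix in which unpopulated rows stay zero and are flagged rather than
normalized. `subject_sweep()` repeats LOPO on seeded random subject
subsets (without replacement, 3 repetitions per size by default) to relate
accuracy to cohort size.

## The synthetic cohort

`make_cohort()` emulates the structure of a 10-subject, 13-activity,
six-point, 60 Hz recording campaign. Each activity is an `activity_spec`:
a motion family, amplitude, frequency, a rotation of the canonical motion
plane, and per-vertex participation weights. Five parametric families
cover the qualitative shapes of the 13 activities:

| family | canonical curve | used for |
|---|---|---|
| planar-circle | circle in a body plane | arm circles |
| linear-oscillation | 1-D sinusoid | arm raises / stretches, leg raises |
| vertical-dip | half-cosine dip with forward sway (an arc) | squats, sumo squats, lunges, arm chest/head crossings |
| lateral-zigzag | triangle wave with per-step bounce | cross / side stepping |
| composite-antiphase | left/right limbs oscillate oppositely | jumping jacks, walking |

Because PCA removes plane orientation and bounding-box normalization
removes absolute amplitude, two classes are distinguishable in image space
only through trajectory *shape* and through *which channels move*. The 13
archetypes are therefore parameterized so that each class has a distinct
(family, active-vertex) signature — e.g. arm raises move one wrist, arm
stretches both, jumping jacks wrists and knees — while deliberately
similar pairs (squats vs. sumo squats, cross vs. side stepping) differ
only in participation weights, which modulate arc aspect and bounce
height. Per-subject heterogeneity is a lognormal amplitude scale
(`subject_variation`, default 0.1) plus a uniform phase offset per class,
seeded by (seed, subject); positional Gaussian noise (default 5 mm SD) is
added on top. A fixed seed makes the whole cohort bit-reproducible.

`imu_from_trajectory()` turns any cohort sequence into a physically
consistent IMU stream (second-central-difference acceleration, gravity
added back, identity or velocity-tangent sensor orientation), feeding the
raw-signal classifiers and the calibration round-trip tests.

**What the simulator does not emulate:** pose-estimation error and its
temporal correlation, soft-tissue and sensor-mounting artifacts, joint
limits, within-class variation in movement *style*, activity transitions
and rest pauses inside windows, and magnetometer/gyroscope noise
characteristics. Passing the end-to-end recovery test therefore shows that
the pipeline's representations and classifiers can separate kinematically
distinct activity archetypes under subject heterogeneity and measurement
noise — not that any particular accuracy transfers to real recordings.

## Problem sizes and reproducibility

The packaged evaluation runs (test suite and `scripts/acceptance.R`) use a
cohort of 6 subjects × 13 classes × 20 s per class at 60 Hz with 5 mm
noise, 16 × 16 rasters for the LOPO runs (the 64 × 64 default is exercised
by the tensor-contract tests), one augmented copy per training sample, and
Adam at $3 \times 10^{-3}$ for up to 14 epochs with patience 3 — sizes
chosen so a full double LOPO run (plain and augmented, 12 model fits)
completes on a single CPU in minutes. All randomness — cohort, validation
subjects, augmentation draws, initialization, shuffling — derives from one
integer seed via an explicit seed-mixing function, and identical seeds
reproduce reports bit for bit in single-threaded numerics.

## Known limitations

* Heatmaps discard direction and speed along the path; activities that
  differ only in pacing or direction collapse to similar images
  (frequency survives only weakly, via crossing counts before
  normalization).
* Per-channel bounding boxes discard absolute amplitude; an activity pair
  differing only in range of motion is not separable in image space.
* The ConvLSTM stack is CPU-bound R; it is sized for desk-scale cohorts,
  not for large datasets.
* The simulator's archetypes are minimal parametric shapes; results on it
  bound what the pipeline can do under ideal pose estimation, not what a
  full pose-estimation front end would achieve.
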