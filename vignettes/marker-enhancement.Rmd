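---
title: "Lifting sparse video keypoints to dense anatomical markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifting sparse video keypoints to dense anatomical markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Markerless motion capture estimates human movement from video. Open-source
2-D pose estimation models detect only a sparse set of body keypoints —
mostly joint centers — and after triangulation these 20 noisy 3-D points
constrain a multi-body skeletal model poorly: many different poses place the
joint centers in nearly the same locations, so inverse kinematics (IK)
produces large joint-angle errors, particularly at the lumbar spine and
hips. Laboratory motion capture avoids this by tracking a dense set of 43
*anatomical* markers (iliac spines, femoral epicondyles, marker clusters,
calcaneus and metatarsal heads, ...) whose geometry pins down segment
orientations.

`markerlift` implements a *marker enhancer*: a learned sequence-to-sequence
mapping from the 20 sparse video keypoints to the 43 dense anatomical
markers, together with everything needed to study it end to end — a
synthetic data generator built on an articulated skeleton, the full data
preparation pipeline, three network architectures with their training
protocol, model scaling and IK, evaluation protocols, and a torque-actuated
planar tracking simulation that estimates ground reaction forces (GRF) and
joint moments from kinematics.

## The two-model decomposition

Two independent networks are trained, mirroring the deployed system:

* the **body model** maps 15 shoulder/lower-body keypoints (47 input
  features per frame: 15 × 3 coordinates + height + weight) to 35
  anatomical markers (105 outputs);
* the **arm model** maps 7 arm/shoulder keypoints (23 features) to 8 arm
  markers (24 outputs).

Both operate on 1-s windows of 60 frames (60 Hz). Marker positions are
expressed relative to a root marker — the midpoint of the two hip
keypoints — then divided by the subject's height, and finally standardized
per feature with training-split statistics. Subject height (m) and mass
(kg) enter as two extra input channels, standardized like any other
feature.

Three architectures are provided, and their trainable-parameter counts pin
the layer structure exactly:

| architecture | body | arm |
|---|---|---|
| linear (per-frame affine) | 5,040 | 576 |
| LSTM (4 / 5 layers × 128 units, affine readout) | 498,409 | 607,256 |
| transformer (2 blocks, 4 heads, embed 256, FF 1024) | 1,618,793 | 1,591,832 |

The LSTM uses one bias vector per gate set (the count 498,409 is only
reproduced with single biases). The transformer uses a *fixed sinusoidal*
positional encoding — a learned positional embedding would add 60 × 256
parameters that the printed counts leave no room for — biased q/k/v/output
projections, a 256→1024→256 feed-forward block, and two post-block layer
normalizations with gain and offset; there is no final stack-level
normalization. All three are implemented directly on base-R matrices with
hand-derived backpropagation; the test suite verifies every gradient
against central finite differences on small configurations.

## Training protocol

The loss is a weighted mean squared error on the standardized outputs with
weight 2 on the nine coordinates of the three markers on each foot (18
features in the body model) and 1 elsewhere; ankle and subtalar angles are
disproportionately sensitive to foot-marker error, which this weighting
reflects. Optimization uses Adam with batch size 64. The linear and LSTM
models use a constant learning rate (6e-5 by default, matching the deployed
system; desk-scale experiments in the tests use a larger rate so that small
models converge in few epochs). The transformer uses the warm-up /
inverse-square-root schedule scaled by the embedding dimension
(`transformer_lr()`), with 4000 warm-up steps. Early stopping monitors the
validation loss with patience 3 and minimum improvement 0, and the
best-validation weights are restored. `select_best_of_two()` implements the
train-twice-select-best protocol on validation RMSE only; ties break to the
lower seed so the selection is deterministic.

Validation RMSE is reported in millimetres on de-normalized positions:
predictions are de-standardized and multiplied by subject height, so the
number is comparable across subjects of different stature.

## The synthetic data generator

No motion-capture corpus ships with the package; `synthesize_corpus()`
generates one. A `skeleton_model` is an articulated segment tree (pelvis
root with 6 degrees of freedom, 3-DOF lumbar, 3-DOF hips, 1-DOF knees,
2-DOF ankles, plus 3-DOF shoulders and 1-DOF elbows; 29 coordinates) whose
geometry is proportional to stature using standard anthropometric
fractions, carrying the 20 keypoints and 43 anatomical markers as
rigidly-attached virtual points. Movement classes emulate the diversity of
a real corpus:

* `gait`: periodic out-of-phase hip/knee/ankle patterns with forward
  progression (stride frequency jittered around 0.9 Hz);
* `squat` / `sit_to_stand` / `jump`: symmetric flexion patterns (one squat
  repetition per 2 s);
* `rolling`: a continuous root rotation sweeping the body through prone and
  supine — the orientation-changing regime where keypoint-only pipelines
  were known to fail;
* `freestyle`: band-limited random motion (sums of 4 sinusoids per
  coordinate, 0.15–1.4 Hz, squashed into the coordinate bounds), with the
  root heading free over ±180°;
* `static`: the zero pose, used for scaling calibration.

Subject stature is drawn uniformly on 1.50–1.95 m and body-mass index on
19–29, values spanning a typical adult population. Each base subject is
emitted at the five uniform scales 0.90/0.95/1.00/1.05/1.10 (quintupling
the corpus); scaled variants share joint trajectories, only the geometry
changes, and variant mass is scaled by the cube of the factor (geometric
scaling of a homogeneous body). Keypoint observation noise is Gaussian with
σ = 18 mm per axis per frame, the noise magnitude validated against real
pose-estimation pipelines.

What the generator does *not* emulate: soft-tissue artifact (markers are
perfectly rigid here), marker occlusion and gaps, pose-estimator outliers
and identity switches, and the kinematic richness of real human movement.
Passing tests on synthetic data therefore demonstrate that the pipeline is
implemented correctly and that its comparative orderings (dense beats
sparse, augmentation helps on rotated movements) hold under the stated
noise model — not that the absolute errors transfer to real video.

## Data preparation order

Windows are cut at 60 Hz, 60 frames long with 50% overlap (hop 30);
remainders shorter than a window are discarded. Noise is injected in metric
units (σ = 0.018 m) on root-centered keypoints *before* height
normalization — a σ quoted in millimetres is only meaningful on metric
coordinates — and never on targets. Rotation augmentation produces 8 copies
per window: six rotations about the vertical axis at 0°, 60°, ..., 300°
(even coverage, since the six angles are otherwise arbitrary) and two
seeded uniformly-random Euler Z-Y-X rotations; the same rotation applies to
inputs and targets and the height/weight channels are untouched.
Standardization statistics come from the training split only. Splits are by
*base subject* — all five scale variants of a subject land in one split —
using largest-remainder rounding with at least one subject per split.
`balance_sources()` caps over-represented sources (here: movement classes)
by seeded uniform subsampling so no single class dominates the training
distribution.

## Scaling and inverse kinematics

`scale_to_static()` fits one global scale factor to a static calibration
frame by nested optimization (golden-section on the factor, full pose IK
inside), never returning a fit worse than the unscaled model.
`solve_ik()` minimizes the weighted squared distances between observed and
model markers per frame by damped Gauss-Newton with analytic geometric
Jacobians, warm-started from the previous frame, with a tiny (1e-6)
quadratic pull toward the previous frame that resolves the gauge freedom of
kinematically redundant poses (e.g. axial rotations of a straight leg).
On noiseless dense markers the FK→IK round trip recovers all 21 analysis
degrees of freedom (pelvis 6, lumbar 3, hips 2×3, knees 2×1, ankles 2×2) to
well under 0.1°.

## Evaluation protocols

`kinematics_rmse()` reports per-DOF RMSE — rotations in degrees, pelvis
translations in millimetres, never mixed — and `summarize_kinematics()`
averages over trials, then degrees of freedom, then activities.
`run_generalizability_protocol()` reproduces the synthetic-keypoint
evaluation: reference kinematics are defined as IK on the noiseless dense
anatomical markers (a protocol substitution for reference models fitted by
an external pipeline), against which keypoints without noise, keypoints
with noise, and each enhancer's predictions are compared, each condition
re-scaled on a static pose observed under that same condition. A leakage
guard errors if the evaluation corpus shares base subjects with an
enhancer's training set.

## The tracking simulation

Dynamics are estimated by tracking reference kinematics with a
torque-actuated planar (sagittal) model: pelvis x/y translation and pitch,
lumbar, and hip/knee/ankle per side (10 coordinates); segment masses,
centers and radii of gyration follow standard anthropometric fractions.
Every non-root joint is driven by an antagonistic pair of torque actuators
with activations in [0, 1], first-order activation dynamics (time constant
50 ms) and torque limits proportional to body mass, so the squared
activations keep the meaning they have in muscle-driven formulations. The
cost integrates effort (w1 on squared activations, w2 on squared
excitations) and tracking terms (w3, w4, w5 on squared deviations of
positions, velocities, accelerations from the filtered reference) over
[t0, tf]; reference derivatives come from spline differentiation. Since the
source formulation never prints its weights, the defaults here
(0.1/0.01/100/1/1e-4) were chosen once so that static standing is tracked
to a fraction of a degree while effort keeps activations small.

Ground contact uses three spheres per foot with a smooth normal force
k·d^{3/2}·(1 + c·v) (k = 1e6, c = 2 s/m, smoothed positive parts) and
tanh-smoothed Coulomb friction (μ = 0.8). Movement-specific options follow
the published formulations: time buffers extend the horizon and are
excluded from metrics (the drop-jump convention of 0.3 s is the natural
default); squats impose periodic pelvis position and speed instead of
buffers; sit-to-stand adds a heel-lift penalty, implemented as the
integrated squared smooth-positive heel-sphere clearance (the functional
form is unstated in the source and this is the simplest smooth choice).

The problem is transcribed by trapezoidal direct collocation with implicit
dynamics: accelerations are decision variables and the defect
ID(q, q̇, q̈) − τ(a) = 0 is enforced per node, with inverse dynamics by a
planar recursive Newton-Euler pass vectorized over mesh nodes. Because no
general NLP solver is available to the package, the nonlinear program is
solved by an augmented Lagrangian over a sparse damped Gauss-Newton inner
solver: all rows except the dynamics (and heel) residuals are linear, so
the Jacobian is a constant sparse matrix plus a node-local block obtained
by finite differences of the dynamics alone (44 evaluations, each
vectorized over all nodes). Bounds are handled by an active-set correction
that re-solves for the free variables with bound-hitting variables fixed.
Converged solutions satisfy all defects below 1e-6 (scaled units: forces by
body weight, torques by body weight × half stature); non-convergence is
flagged, never silent, and flagged results are refused by the reporting
functions. GRF are reported in %BW and joint moments in %BW·ht.

Default problem sizes in the tests — 14–16 mesh intervals over 1–2 s
horizons, 20 base subjects for the training experiments, 1×64-unit LSTMs —
were chosen as the smallest sizes at which the studied orderings are
stable and reproducible.

## Numerical choices and edge cases

* Weight initialization: uniform fan-in scaling, seeded; biases zero,
  layer-norm gains one. No dropout anywhere — the small models used at
  this scale do not overfit before early stopping triggers, and inference
  stays deterministic.
* Inference windows: 50% overlap plus one tail window aligned to the final
  frame so every frame is covered; overlapping predictions are averaged
  uniformly (the deployed system does not state its blending).
* Zero-variance features get standard deviation 1 and are flagged.
* Sequences shorter than 60 frames are rejected by `enhance()` (too short)
  and yield zero windows in training.
* The IK line search treats a stalled step at negligible gradient as
  convergence; only running out of iterations mid-descent flags a frame,
  which is then interpolated from its neighbours with a warning.
* `lowpass_filter()` is a forward-backward 4th-order Butterworth
  (zero phase) with reflection padding; cutoffs at or above Nyquist error.

## Worked example

```{r example}
library(markerlift)

corpus <- synthesize_corpus(
  corpus_config(6, c(gait = 0.4, squat = 0.3, freestyle = 0.3),
                trials_per_subject = 1, duration = 3), seed = 11)
splits <- split_by_subject(corpus, c(0.8, 0.1, 0.1), seed = 2)

train_w <- make_training_windows(splits$train, "body", seed = 5)
val_w <- make_training_windows(splits$val, "body", augment = FALSE, seed = 6)
stats <- fit_norm_stats(train_w)

cfg <- enhancer_config("lstm", "body", lstm_layers = 1, lstm_units = 64,
                       learning_rate = 3e-3, max_epochs = 15)
run <- train_enhancer(build_enhancer(cfg, seed = 1),
                      collate_windows(train_w, stats),
                      collate_windows(val_w, stats), seed = 1)
glance(run)
autoplot(run)
```

## Known limitations

* The skeleton's marker placements are plausible but schematic; only the
  counts (20 keypoints, 43 anatomical markers, 3 per foot) and the
  body/arm split are structurally binding.
* The tracking model is planar: medio-lateral forces and non-sagittal
  moments are out of scope, and the lumped torso ignores arm dynamics.
* The solver is a desk-scale replacement for an interior-point NLP solver;
  very long horizons (hundreds of mesh intervals) become slow in R.
* Absolute accuracies on synthetic data do not transfer to real video;
  only implementation correctness and comparative orderings are claimed.
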