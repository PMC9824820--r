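---
title: "Classifying exercises from pose keypoint time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying exercises from pose keypoint time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the data model

Single-camera pose-detection models emit, per video frame, a 33-landmark
skeleton in which each landmark is a four-vector $K_i = (x, y, z, v)$:
image-plane coordinates, an estimated depth on the same scale as $x$, and
a visibility score in $[0, 1]$. A recording is therefore a multivariate
time series $X = \{K_1, \dots, K_{33}\}$ which, flattened
keypoint-major/axis-minor, has 132 channels
$(k_{1x}, k_{1y}, k_{1z}, k_{1v}, \dots, k_{33v})$. The task is 7-class
classification: which exercise of a rehabilitation protocol (low-back or
shoulder) is being performed. Classification operates on fixed-width
windows cut from the recording, so a deployed system can score an
arbitrary-length video as a stream of windows.

`poseclass` is unit-agnostic about the image coordinates (pixels or
normalised units both work): every downstream step is either per-channel
(resampling, features) or removes location/scale structure explicitly
(the body-centric transforms, feature standardisation, batch norm).

# Preprocessing

**Resampling.** Recordings arrive at whatever frame rate the camera and
pose backend produced (typically ~30 Hz, sometimes irregular). Each of
the 132 channels is interpolated independently with an interpolating
cubic spline (`stats::splinefun`, `method = "fmm"`) and evaluated on a
uniform grid that starts at the first timestamp and steps by
`1/rate_hz`; nothing is extrapolated past the last timestamp. The FMM
end condition reproduces polynomials up to degree 3 exactly, which the
test suite verifies; a natural spline would distort cubic trends near
the record boundaries. Visibility is clipped back into $[0,1]$ after
interpolation. At least 4 frames are required; shorter inputs are an
error rather than a guess.

**Body-centric transforms.** Two optional transforms remove the
subject's position and orientation in the image:

* *translate* — subtract the per-frame hip midpoint
  $K_o = (K_{\mathrm{lhip}} + K_{\mathrm{rhip}})/2$ from every landmark.
  Applying it twice is a no-op (the midpoint is already at the origin),
  which is tested.
* *translate_rotate* — additionally rotate each frame into an
  orthonormal basis whose $x$–$y$ plane contains both shoulders and
  $K_o$. The constraint "shoulders and origin in the $x$–$y$ plane" does
  not determine the basis uniquely, so the package fixes the minimal
  construction: with hip-translated shoulders $s_l, s_r$, let
  $u = s_r - s_l$ and $c = (s_l + s_r)/2$; then $\hat x = u/\lVert u\rVert$,
  $\hat z = (u \times c)/\lVert u \times c\rVert$,
  $\hat y = \hat z \times \hat x$, and $R$ stacks
  $(\hat x, \hat y, \hat z)$ as rows. This is right-handed, puts both
  shoulders at $\hat z$-coordinate 0, and makes the canonical
  coordinates invariant to any global proper rigid motion of the scene
  (verified to $10^{-6}$ on random inputs). The left-to-right shoulder
  order fixes the sign of $\hat x$; either convention is consistent and
  classification is unaffected.

The basis is recomputed independently every frame — no temporal
smoothing — and the visibility channel passes through bit-exactly. A
degenerate frame (shoulders coincident, or collinear with the origin,
norms below $10^{-8}$) reuses the previous frame's rotation (identity if
it is the first frame) and is reported with its index: continuity was
preferred over failure because single bad frames are common in real pose
output.

**Segmentation.** Sliding windows start at offsets $0, s, 2s, \dots$;
a record of $n$ samples yields $\lfloor (n - w)/s \rfloor + 1$ windows,
each inheriting the record's label, subject and camera angle. Records
shorter than one window are dropped with a warning, not padded — padding
would fabricate motion. Defaults are $w = 400$ samples (16 s at 25 Hz)
and $s = 50$ samples (2 s); the small stride is deliberate overlap
augmentation. Window counts and contents are tested against a
brute-force enumeration of every offset.

# Classifiers

**Engineered-feature linear SVM.** Eleven summary features are computed
per channel: mean, median, absolute energy $\sum x_t^2$, standard
deviation, variance, minimum, maximum, skewness, excess kurtosis, mean
spectral energy (mean of $|\mathrm{DFT}(x)|^2$), and the number of
crossings of the channel mean. Moments are population moments
(denominator $W$); a zero-variance channel gets skewness and kurtosis 0
by convention. The implementation is vectorised across all windows and
channels and is checked against a naive one-formula-at-a-time oracle to
$10^{-9}$. "Mean spectral energy" was chosen over the other plausible
reading of the abbreviation (mean squared error about the mean); by
Parseval's theorem it is proportional to absolute energy, so the choice
does not change what the feature set can express. Features are
standardised to zero mean and unit variance *using training-fold
statistics only* (avoiding leakage; constant features are centred and
left unscaled) and fed to a linear-kernel SVM with $C = 0.025$ via
`e1071::svm`. libsvm's multiclass strategy is one-vs-one voting; with
seven well-separated classes this is interchangeable with one-vs-rest,
and it is what the installed, battle-tested implementation provides.

**1D convolutional network.** The second classifier is the standard
fully-convolutional time-series baseline:
Conv1D(128, k=8) → BN → ReLU → Conv1D(256, k=5) → BN → ReLU →
Conv1D(128, k=3) → BN → ReLU → global average pooling → L2
normalisation → dense softmax, trained with Adam on categorical
cross-entropy for a fixed 50 epochs (no early stopping) at learning rate
0.005. The kernel sizes 8/5/3 follow that baseline architecture's
convention. Global average pooling makes the network accept any window
width at least as large as the largest kernel and is what confers
robustness to temporal translation: the suite checks that circularly
shifting test windows by up to half a window changes fewer than 5% of
predicted labels on a converged model.

No deep-learning framework is involved: convolutions are im2col matrix
products against BLAS, with hand-derived analytic gradients for every
layer, verified against central finite differences to ~$10^{-8}$
relative error. Numerical choices: "same" zero padding with left pad
$\lfloor (k-1)/2 \rfloor$; batch-norm variance floor $10^{-3}$ and
running-statistics momentum 0.9 (statistics are frozen at prediction
time); L2-normalisation floor $10^{-12}$; Adam with
$\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$ and bias
correction; He-normal initialisation for convolutions and
Glorot-uniform for the dense layer; batch size 32, with a trailing
singleton batch folded into its predecessor because batch norm is
undefined on one sample. Everything — initialisation, shuffling,
training — is a deterministic function of the config seed, so the same
seed reproduces the same model bit for bit.

# Evaluation protocol

Folds are assigned to *subjects*, not recordings: subjects are shuffled
with a fixed seed and partitioned into $k = 5$ groups as evenly as
possible (21 subjects give fold sizes 5/4/4/4/4). The same assignment is
reused across every experimental condition so that conditions are
compared on identical splits, and the suite asserts that train and test
subjects never intersect anywhere. The score is class-balanced accuracy
— the unweighted mean of per-class recalls over classes present in the
test labels — which is insensitive to the imbalance introduced by
asymmetric exercises (5 repetitions per side versus 10 bilateral). No
reweighting is applied during training; imbalance is handled at scoring
time only. Scoring is at window (segment) level, since that is what the
models classify. Reported intervals are Student-t:
$\bar a \pm t_{0.975,\,k-1}\, s/\sqrt{k}$ — the natural choice for a
mean over five fold scores.

Four experiment harnesses wrap this engine: keypoint subsets (five
registered sets, single camera angle), coordinate transforms,
camera-angle robustness (stage 1 trains on one angle and tests both;
stage 2 trains on both), and training saturation (seeded subject
subsampling within each training fold, the held-out fold fixed across
sizes). The grid search enumerates channels × keypoint set × transform ×
window width × learning rate in that order and breaks ties toward the
earliest row. Because the grid reuses the same 5-fold CV rather than a
nested inner split, its selected configuration is potentially
optimistic; that caveat applies equally to any non-nested grid search.

# The synthetic data generator

Real study videos of human subjects cannot be redistributed, so the
package ships a seeded simulator that reproduces the statistical
*structure* the pipeline relies on, and its defaults encode the study
protocol: 7 classes per task, 10 repetitions per record (asymmetric
exercises: half-duration records per side), 60 s records at 30 Hz
(so the 25 Hz resampler is genuinely exercised), two camera angles
67.5° apart (within the protocol's 45–90° spacing), and 12 subjects by
default.

Each class is a set of per-landmark sinusoidal joint programs (amplitude
3-vector, frequency in repetition range 0.05–2 Hz, phase, baseline
posture offset) on a neutral standing 33-landmark template; face, hand
and foot landmarks follow the nose, wrists and ankles so the whole
skeleton moves coherently. Subject variation is multiplicative on body
scale (±10%) and frequency (±15%) and additive on phase and posture —
enough to make subject-grouped CV a real generalisation test without
destroying class separability. The camera is orthographic with a yaw
parameter: world motion depends only on the motion seed, never the
angle, so two viewpoints of a record are *exactly* rigidly related
before noise — giving the transform-invariance tests a clean oracle
(perspective distortion would break exactness and is deliberately
excluded). Gaussian noise is added per channel with the depth channel
5× noisier than the image plane (the qualitative behaviour of
single-camera depth estimates; no quantitative magnitude is available,
so the ratio is exposed in the config). Visibility is drawn near 0.95
with dips toward 0.5 for the ~10% most distant landmarks per frame.

Two deliberate design points: the two lower-body low-back classes
(`pelvic_tilt`, `lumbar_rotation`) share an identical pelvis program and
differ only at the knees and ankles, so the upper-body-only keypoint set
*provably* cannot separate them — this reproduces the expected
degradation of upper-body-only models with a known mechanism. And class
frequencies/joint sets are mutually distinct enough that a
nearest-centroid classifier on per-channel spectral peaks already
separates the classes; the suite asserts this, which is what makes the
downstream "CNN reaches ≥ 0.9" checks meaningful rather than vacuous.

What the simulator does **not** emulate: perspective and lens
distortion, pose-estimator failure modes beyond Gaussian noise and
visibility dips (identity switches, dropped frames, occlusion-correlated
bias), biomechanical joint limits, within-record tempo drift, and
between-class confusability as high as real exercise protocols exhibit.
Consequently, passing end-to-end tests demonstrates that the pipeline is
correct and that its qualitative claims (viewpoint sensitivity,
keypoint-subset dependence, saturation) have the right mechanisms — it
does not certify real-world accuracy figures.

# Demonstration scale

The end-to-end runs in the test suite and in `scripts/acceptance.R` use
a scale chosen to exercise every component in a few minutes of CPU time:
12 subjects, 32 s records, both camera angles (216 records, ~1300
windows), 4 s non-overlapping windows over the 12 major joints with
x/y/z channels, and a narrower, shorter-schedule CNN (64/128/64 feature
maps, 6 epochs) than the full-size default (128/256/128, 50 epochs).
On this data the small network is already past convergence (final
training loss < 0.1) and both classifiers reach ceiling on held-out
subjects; nothing in the checked properties depends on the larger
architecture, which remains the default for real data. The camera-angle
demonstration uses the engineered-feature SVM because the viewpoint
effect is a property of the *representation* (raw image coordinates),
not of the classifier, and the SVM makes the experiment cheap; the
saturation experiment uses the CNN, whose appetite for training
subjects is the question being asked.

# Known limitations

* The pose backend adapter is a contract, not an implementation: the
  package classifies keypoint time series and deliberately does not
  decode video or run pose estimation.
* The rotation transform propagates depth noise into all three rotated
  axes; no depth rescaling or filtering is applied before rotation.
  With noisy real depth this is a known weakness of rotation-based
  normalisation.
* Gap-filling, jitter rejection and temporal smoothing are out of
  scope; records are assumed to be contiguous.
* Record-level aggregation (e.g. majority vote over a recording's
  windows) is left to the caller; all reported scores are per window.
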