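---
title: "Identifying coordinate frames from multi-voxel activity patterns"
author: "coordFrames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying coordinate frames from multi-voxel activity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordFrames)
```

## The scientific question

When a person aims a wrist force at a visual target, the brain must convert
the target's location from a frame fixed to the external world (the
*extrinsic* frame) into the frame of the muscles that produce the force (an
*intrinsic* frame). A region that encodes the aiming direction extrinsically
is unaffected when the forearm is rotated between a pronated ("Pro") and a
midway ("Mid") posture; a region whose frame is attached to the limb rotates
with it — fully for a *joint-like* frame (90° for a 90° posture change),
partially for a *muscle-like* frame, because wrist-muscle pulling directions
rotate by less than the joint does.

`coordFrames` quantifies where a region sits on this continuum with a single
number, the **coordinate index** $\Delta\hat\theta$: the rotation of the
region's decoded aiming direction induced by the posture change. 0° indicates
an extrinsic frame, 90° a joint-like frame, and intermediate values a
muscle-like frame.

## The rotation-model common decoder

Let $\mathbf r^{Pro}, \mathbf r^{Mid} \in \mathbb R^N$ be the multi-voxel
activity patterns of a region under the two postures and
$\mathbf v = (\cos\theta, \sin\theta)^\top$ the vectorial representation of
the instructed aiming direction $\theta$ in the extrinsic frame. The *common
decoder* is a single linear map $\mathbf w$ (2 × N) shared by the two
postures, with a rotation applied to the Mid-posture prediction:

$$\mathbf v = \mathbf w\,\mathbf r^{Pro} = R(\Delta\theta)\,\mathbf w\,\mathbf r^{Mid},
\qquad
R(\Delta\theta)=\begin{pmatrix}\cos\Delta\theta & -\sin\Delta\theta\\
\sin\Delta\theta & \cos\Delta\theta\end{pmatrix}.$$

Rearranged for estimation, Pro samples are paired with the target
$\mathbf v$ and Mid samples with $R(-\Delta\theta)\mathbf v$, and one
penalized linear regression is fitted on the stacked design
(`fitCommonDecoder()`). Sweeping $\Delta\theta$ from −45° to 315° in 5° steps
(`errorCurve()`) and measuring the cross-validated mean squared error of the
predicted aiming vector traces an error curve whose minimizer is
$\Delta\hat\theta$ (`estimateCoordinateIndex()`). Group-level inference uses
circular statistics across participants (`groupCoordinateIndex()`).

### Cross-validation structure

The outer loop leaves one run of each posture out as the test set. Within
each outer fold, an inner leave-one-run-pair-out loop selects the
regularization strength from a fixed grid (default $10^{-2} \dots 10^{3}$,
six log-spaced values), scoring each candidate by its mean inner-fold error
over a coarse 45°-spaced angle lattice; a single strength per outer fold
keeps the error curve comparable across angles. The reported curve is the
mean over outer-fold test errors, so the angle is selected on outer-test
error. An optional fully nested mode (`fullyNested = TRUE`) additionally
selects the angle on the inner folds of each outer fold, as a bias check;
`wFit = "full"` instead fits once per angle on all runs and reports
in-sample error. Both alternatives are labeled in the returned object.

### Estimator family

The decoder family is linear with a penalty switch: the default is a ridge
penalty, whose closed-form solution is linear in the rotated targets — one
eigendecomposition of each fold's centered Gram matrix therefore evaluates
the entire 73-point angle grid and the whole regularization path with small
matrix products, keeping the nested sweep fast and exactly deterministic. A
sparsity-promoting alternative (`penalty = "lasso"`, an L1 penalty grouped
across the two output dimensions so voxels are selected jointly) is
available through glmnet; on data with a genuine rotation structure the two
families locate the same minimizer, because the index is driven by the
rotation model and the cross-validation structure rather than by the prior
on the weights. A fitted 2-vector intercept is always included (targets are
not centered), and the prediction's norm is unconstrained — only its
direction carries the frame information.

### Numerical choices

* Loss: squared Euclidean distance between the predicted 2-vector and the
  unit target vector, averaged over test samples; rotating the Mid
  prediction by $R(\Delta\theta)$ before comparison is norm-identical to
  rotating the target the other way, which is what the vectorized
  implementation does.
* Ties at the curve minimum break toward the smallest absolute angle
  (closest to extrinsic), and equal magnitudes resolve to the positive
  angle; the rule is deterministic and recorded here.
* A curve that is flat to within a relative 1e-12 is flagged
  `uninformative` and the index is `NA` — mirroring regions whose error
  functions carry no rotation information rather than inventing an angle.
* Negative eigenvalues of a centered Gram matrix (numerical noise) are
  clamped at zero before the ridge shift is added.

## Sign conventions (one place, applied once)

All angles are degrees at every interface. Direction labels live on the
task's eight-target lattice (0°, 45°, …, 315°), with 0° the extension
direction under the pronated posture. A **positive coordinate index means
the frame rotates with the arm in the direction in which the empirical
muscle rotation is reported** (clockwise in task coordinates). Concretely,
the generator rotates unit preferred directions by $+\Delta\theta_{true}$ in
label units from Pro to Mid, so the Mid pattern for label $\theta$ equals
the Pro pattern for label $\theta-\Delta\theta_{true}$; with the standard
rotation matrix above, the common decoder then recovers
$\Delta\hat\theta = \Delta\theta_{true}$. The EMG module states its own
convention explicitly: `pdShift()` returns
$\mathrm{wrap}_{(-180,180]}(\mu_{Pro}-\mu_{Mid})$, so a clockwise rotation of
a muscle's preferred direction is positive there too.

A consequence worth spelling out: for a label classifier, training on Mid
and testing on Pro places the prediction offsets at $+\Delta\theta_{true}$,
while the reverse transfer mirrors them at $-\Delta\theta_{true}$. Pooling
the two signed profiles would cancel the effect, so the pipeline reports the
Mid→Pro transfer as the canonical signed profile and computes the
across-posture asymmetry index as the sign-aligned average
$(\mathrm{index}_{Mid\to Pro} - \mathrm{index}_{Pro\to Mid})/2$.

## Label decoding and the asymmetry index

`generalizationProfile()` classifies the eight aiming directions with a bank
of eight one-vs-rest binary linear SVMs (fixed C = 1, no per-feature
rescaling since samples are standardized upstream; prediction ties break
toward the smallest label angle). Within-posture profiles use
leave-one-run-out cross-validation; across-posture profiles train on all
runs of one posture and test on all runs of the other, since the two
postures' runs are disjoint and no run-wise fold structure links them. Each
prediction contributes its signed offset (predicted − true, wrapped to
(−180°, 180°]) to an eight-bin profile. The **asymmetry index** is the mean
fraction at +45°/+90°/+135° minus that at −45°/−90°/−135°; the 0° bin is the
peak rather than an error and the 180° bin has no sign, so both are
excluded. `asymmetryContrast()` compares within- vs across-posture indices
across participants with a paired t-test, Bonferroni-corrected by a caller-
supplied family size (a nine-region family in the motivating analyses).

## EMG tuning and circular statistics

Trial-mean muscle activations are fitted with the cosine tuning model
$f(\theta)=k\cos(\theta-\mu)+b$ via the exact linear reparameterization
$f = A\cos\theta + B\sin\theta + b$ — closed form, no iterative optimizer,
amplitude nonnegative by absorbing sign into $\mu$ (`fitCosine()`). Fits
with amplitude below 1e-9 of the response scale are flagged untuned with
$\mu$ undefined rather than returning an arbitrary angle.

Circular summaries use the mean resultant vector; the 95% CI of the mean
direction uses the standard dispersion-based large-sample formula, with a
seeded 10,000-resample bootstrap percentile interval as fallback when the
resultant is too weak for the closed form. The one-sample test against a
reference direction is a bootstrap sign-type test (the smaller tail fraction
of resampled mean directions around the reference, doubled, with add-one
smoothing) reported together with a CI-inclusion decision; it assumes no
parametric circular distribution, which suits the small per-group sample
sizes (6 muscles, 12 participants). The exact method used is recorded in
every output.

## The synthetic study

No recordings ship with the package, so `simulateStudy()` generates data
with exactly the statistical structure the analysis assumes:

* **Population code**: each voxel pools its own block of
  `nNeuronsPerVoxel` cosine-tuned units (preferred directions uniform on the
  circle; amplitudes and baselines uniform in configurable ranges) with
  nonnegative weights normalized to sum to one, plus i.i.d. Gaussian trial
  noise. This is the minimal generative model consistent with the
  population-code premise that a voxel's directional tuning is a mixture of
  its units' tuning curves.
* **Frame rotation**: from Pro to Mid every unit's preferred direction
  rotates by `deltaThetaTrue` plus unit-specific Gaussian jitter (default sd
  10°), so the simulated muscle-like frame has a realistic spread rather
  than a rigid rotation. Intermediate rotations (e.g. 58.8°) are allowed
  even though labels stay on the 45° lattice.
* **Design**: 8 runs per posture of 32 trials (8 directions × 4
  repetitions, randomized order per run), 12 participants, mirroring the
  motivating experiment's 7–9 runs per posture and 32-block runs. Trial
  responses are the primary exchange format.
* **Defaults**: 200 voxels, 20 units/voxel, amplitudes 0.5–1.5, noise sd
  0.3. With sum-to-one mixing the effective per-voxel tuning amplitude is
  roughly $\bar k/\sqrt{m}\approx 0.22$, so the per-voxel signal-to-noise
  ratio is below 1 while the 200-voxel population is strongly decodable —
  chosen for testability (real per-ROI voxel counts and SNR are unknown and
  BOLD noise is far more structured).

The time-series mode (`generateTimeseries()`) exists only to exercise the
signal-conditioning pipeline: each run is rendered at TR = 2 s as 20 s rest
at a configurable baseline plus linear drift, 6 s blocks (3 volumes) whose
pattern enters 4 s late to emulate the hemodynamic lag, and 6 s terminal
rest that absorbs the delayed tail — the inverse of the preprocessing
pipeline up to noise. There is no hemodynamic convolution beyond the fixed
delay, no physiological noise, and no head motion.

What passing tests therefore show: the estimator recovers a known frame
rotation from data with cosine population-code structure at realistic
design sizes, and every pipeline stage is internally consistent. What they
do not show: robustness to structured BOLD noise, motion, or violations of
cosine tuning.

## Signal conditioning

The stage order is fixed: hemodynamic shift (4 s earlier, a whole number of
volumes) → baseline normalization (divide each voxel by its mean over the
initial 20 s rest; degenerate baselines raise an error naming the voxel) →
linear detrending → per-block pattern extraction (one sample per task
volume by default, or one averaged sample per trial) → per-sample
z-scoring across features (standardizing each volume's voxel vector, which
removes global activation differences between postures; zero-variance
samples are zeroed, logged in the object metadata and warned about, rather
than dropped, so feature indices stay stable).

One deliberate choice: the detrending line is estimated **from the rest
volumes only** (initial and terminal rest) and removed from the whole run,
preserving the run mean. A whole-run least-squares fit would absorb part of
the task-evoked signal into the trend — the pattern content biases the
fitted slope by far more than the round-trip tolerance — whereas the
rest-only fit removes exactly the injected drift and leaves a noiseless
rendered run recoverable to machine precision (`method = "all"` provides
the whole-run variant).

## Problem sizes used by the test suite

The validation suite regenerates everything from code: parameter recovery
runs 12 participants × 20 seeds at each of four ground-truth rotations (0°,
30°, 58.8°, 90°) at the 200-voxel study scale; profile and asymmetry checks
use the same scale with fewer replicates; exactness checks (cosine fits,
circular means vs a brute-force oracle, rotation algebra, least-squares
equivalence at vanishing regularization, preprocessing round trips) run on
small closed-form instances. The ridge fast path makes a full nested error
curve for one participant a sub-second computation, which is what makes the
recovery study practical.

## Known limitations

* The generator's linear mixing + i.i.d. noise is optimistic relative to
  BOLD data; recovered-index precision on real recordings will be lower.
* The across-posture asymmetry's sign convention is meaningful only under
  the package's canonical transfer direction; pooled unsigned summaries are
  available via `poolProfiles()` but discard the sign.
* The bootstrap one-sample test is approximate for very small n (< 5) and
  the dispersion-based CI assumes a unimodal sample; both fall back or warn
  rather than fail silently.
* `errorCurve()` requires at least 3 runs per posture for the nested
  selection; with exactly paired run counts the fold pairing is by sorted
  run order, and surplus runs of the larger posture always stay in training.
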