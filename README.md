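# coordFrames

Identification of the coordinate frame — extrinsic, joint-like, or
muscle-like — embedded in a neural region's multi-voxel activity pattern
during a two-posture isometric wrist aiming task.

## The problem and who this is for

In a visually guided wrist task, targets appear at eight directions (45°
apart) and the task is performed under two forearm postures: pronated
("Pro") and midway ("Mid", supinated ~90° from Pro). A cortical region that
encodes the aiming direction in a frame fixed to the world is unaffected by
the posture change; a region whose frame is attached to the limb rotates
with it — by the full 90° for a joint-like frame, or partially for a
muscle-like frame (wrist-muscle preferred directions rotate clockwise by
roughly 59° for this posture change). This package is for researchers doing
multivariate fMRI/EMG analyses of such paradigms who want a quantitative
index of where a region's frame lies on that continuum, plus a fully
synthetic test bed for the whole pipeline.

## The model at the core

The **common decoder** is a single linear map **w** (2 × N) from an
N-voxel pattern **r** to the 2-D vectorial representation
**v** = (cos θ, sin θ)ᵀ of the aiming direction, shared by the two postures
up to a rotation of the Mid-posture prediction:

    v = w r^Pro = R(Δθ) w r^Mid,   R(Δθ) = [cos Δθ  −sin Δθ; sin Δθ  cos Δθ]

For each candidate Δθ on a grid (−45° to 315° in 5° steps), **w** is fitted
by penalized linear regression on the stacked two-posture design (ridge by
default, grouped lasso optionally), with nested leave-one-run-out
cross-validation: outer folds measure the prediction error of the aiming
vector, inner folds select the regularization. The error curve's minimizer
is the **coordinate index** Δθ̂ of the region: 0° = extrinsic, 90° =
joint-like, intermediate = muscle-like. Group inference uses circular means,
dispersion-based 95% CIs, and bootstrap one-sample tests.

Supporting analyses: cosine tuning fits f(θ) = k·cos(θ − µ) + b for EMG
preferred directions and their posture-induced shifts; one-vs-rest linear
SVM decoding of direction labels with within-/across-posture generalization
profiles and an asymmetry index (mean fraction at +45/+90/+135° offsets
minus −45/−90/−135°); and the raw-series conditioning chain (hemodynamic
shift → baseline normalization → detrending → pattern extraction →
z-scoring). A population-code generator (cosine-tuned units, linearly mixed
into voxels, preferred directions rotated by a known angle under posture
change) makes every stage testable without data.

## Worked example

```r
library(coordFrames)

# Simulate a small study whose true frame is muscle-like (58.8° clockwise)
cfg <- syntheticConfig(nParticipants = 3, nVoxels = 100, nNeuronsPerVoxel = 10,
                       deltaThetaTrue = 58.8, runsPerPosture = 4, seed = 2)
study <- lapply(simulateStudy(cfg), zscorePatterns)

# Coordinate index per participant and at the group level
hats <- sapply(study, function(x) errorCurve(x)@deltaThetaHat)
hats
#> [1] 55 60 60
grp <- groupCoordinateIndex(hats, references = c(0, 90))
grp$summary
#> CircularSummary: mean 58.33 deg +/- 2.67 (95% CI, fisher), R = 0.999, n = 3
grp$tests
#>   reference     pValue ciContainsReference
#> 1         0 0.00019998               FALSE
#> 2        90 0.00019998               FALSE
```

Each participant's error curve bottoms out within one 5° grid step of the
generative 58.8° rotation; the group mean is 58.3° with a 2.7° CI, and the
bootstrap tests reject both the extrinsic (0°) and joint-like (90°)
reference frames — the region is muscle-like.

```r
# Across-posture label decoding shows the same rotation as an offset shift
prof <- generalizationProfile(study[[1]], "Mid", "Pro")
prof
#> GeneralizationProfile (train Mid, test Pro, n = 128)
#> -135deg  -90deg  -45deg    0deg   45deg   90deg  135deg  180deg
#>  0.0000  0.0000  0.0000  0.0469  0.6562  0.2969  0.0000  0.0000
asymmetryIndex(prof)
#> [1] 0.3177083
```

The predicted labels pile up at +45°/+90° (58.8° falls between them), and
the asymmetry index is strongly positive. The EMG side recovers the same
angle from simulated muscle tuning curves:

```r
emg <- generateEmg(truePdPro = c(20, 100, 210, 320), pdShift = 58.8,
                   amplitude = 2, baseline = 5, noiseSd = 0.1, seed = 2)
fitEmgTuning(emg)$summary
#> CircularSummary: mean 58.60 deg +/- 0.85 (95% CI, fisher), R = 1.000, n = 4
```

`runExperiment(config)` chains all stages (simulate → standardize → decode
→ estimate → summarize) from a single list or YAML configuration and writes
TSV tables plus a JSON manifest; `makeReport(dir)` prints a human-readable
summary of a result bundle. The methods vignette
(`vignettes/coordinate-frames.Rmd`) documents the model, the sign
conventions, the cross-validation structure, and what the synthetic
generator does and does not emulate.

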