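test_that("linearly separable noiseless data is classified perfectly in training", {
  cfg <- noiselessConfig(runsPerPosture = 2)
  x <- makeTrials(cfg, zscore = TRUE)
  pro <- x[, posture(x) == "Pro"]
  clf <- trainDirectionClassifier(pro)
  expect_equal(mean(predictDirections(clf, pro) == aimDirection(pro)), 1)
})

test_that("training requires every label and at least two runs", {
  cfg <- noiselessConfig(runsPerPosture = 2)
  x <- makeTrials(cfg)
  pro <- x[, posture(x) == "Pro"]
  expect_error(trainDirectionClassifier(pro[, aimDirection(pro) != 90]),
               "label 90 missing")
  expect_error(trainDirectionClassifier(pro[, runId(pro) == 1]),
               "at least 2 runs")
})

test_that("permuted labels decode at chance level (1/8)", {
  cfg <- noisyConfig(seed = 41, runsPerPosture = 4)
  x <- makeTrials(cfg, zscore = TRUE)
  cd <- SummarizedExperiment::colData(x)
  set.seed(4)
  cd$direction_deg <- sample(cd$direction_deg)
  SummarizedExperiment::colData(x) <- cd
  prof <- generalizationProfile(x, "Pro", "Pro")
  acc <- prof@fraction[prof@offsets == 0]
  expect_lt(abs(acc - 0.125), 0.07)
})

test_that("within-posture accuracy is well above chance at the default noise level", {
  for (s in 1:5) {
    cfg <- syntheticConfig(nParticipants = 1, deltaThetaTrue = 58.8, seed = s)
    x <- makeTrials(cfg, zscore = TRUE)
    prof <- generalizationProfile(x, "Pro", "Pro")
    expect_gt(prof@fraction[prof@offsets == 0], 0.5)
  }
})

test_that("noiseless extrinsic data transfers across postures with no offset", {
  cfg <- noiselessConfig(deltaThetaTrue = 0, runsPerPosture = 2)
  x <- makeTrials(cfg, zscore = TRUE)
  prof <- generalizationProfile(x, "Pro", "Mid")
  expect_equal(prof@fraction[prof@offsets == 0], 1)
  expect_equal(sum(prof@fraction), 1)
})

test_that("pure-noise features give near-uniform profiles", {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 60, nNeuronsPerVoxel = 5,
                         tuningAmplitudeRange = c(0, 0), noiseSd = 1,
                         runsPerPosture = 4, seed = 19)
  profs <- lapply(1:3, function(s) {
    x <- makeTrials(syntheticConfig(nParticipants = 1, nVoxels = 60,
                                    nNeuronsPerVoxel = 5,
                                    tuningAmplitudeRange = c(0, 0),
                                    noiseSd = 1, runsPerPosture = 4,
                                    seed = 19 + s),
                    zscore = TRUE)
    generalizationProfile(x, "Pro", "Mid")
  })
  pooled <- poolProfiles(profs)
  se <- sqrt(0.125 * 0.875 / pooled@nTest)
  expect_true(all(abs(pooled@fraction - 0.125) < 3 * se + 0.02))
  expect_equal(sum(pooled@fraction), 1, tolerance = 1e-9)
})

test_that("a 90-degree joint-like frame shifts the across-posture mode to +90", {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 100,
                         nNeuronsPerVoxel = 10, deltaThetaTrue = 90,
                         pdRotationJitterSd = 5, noiseSd = 0.3,
                         runsPerPosture = 4, seed = 23)
  x <- makeTrials(cfg, zscore = TRUE)
  profMP <- generalizationProfile(x, "Mid", "Pro")
  expect_equal(profMP@offsets[which.max(profMP@fraction)], 90)
  # reverse transfer mirrors the offset
  profPM <- generalizationProfile(x, "Pro", "Mid")
  expect_equal(profPM@offsets[which.max(profPM@fraction)], -90)
  # within-posture profiles stay centered regardless of the frame rotation
  profW <- generalizationProfile(x, "Mid", "Mid")
  expect_equal(profW@offsets[which.max(profW@fraction)], 0)
})

test_that("the asymmetry index is zero for symmetric profiles and reads off mass", {
  mk <- function(fr) new("GeneralizationProfile",
                         offsets = c(-135, -90, -45, 0, 45, 90, 135, 180),
                         fraction = fr, trainPosture = "Pro",
                         testPosture = "Mid", nTest = 100L)
  sym <- mk(c(0.05, 0.1, 0.15, 0.4, 0.15, 0.1, 0.05, 0))
  expect_equal(asymmetryIndex(sym), 0)
  spike <- mk(c(0, 0, 0, 0.7, 0.3, 0, 0, 0))
  expect_equal(asymmetryIndex(spike), 0.1)
  # the 0 and 180 degree bins are excluded
  extremes <- mk(c(0, 0, 0, 0.5, 0, 0, 0, 0.5))
  expect_equal(asymmetryIndex(extremes), 0)
})

test_that("a clockwise-rotated frame yields a positive across-posture asymmetry index", {
  cfg <- syntheticConfig(nParticipants = 1, deltaThetaTrue = 58.8, seed = 31,
                         runsPerPosture = 4, nVoxels = 100,
                         nNeuronsPerVoxel = 10)
  x <- makeTrials(cfg, zscore = TRUE)
  idx <- asymmetryIndex(generalizationProfile(x, "Mid", "Pro"))
  expect_gt(idx, 0)
})

test_that("the asymmetry contrast handles identical, degenerate and shifted pairs", {
  expect_error(asymmetryContrast(1:4, 1:5), "pairing error")
  expect_error(asymmetryContrast(1:2, 1:2), "size error")
  same <- asymmetryContrast(c(0.1, 0.2, 0.3, 0.15), c(0.1, 0.2, 0.3, 0.15))
  expect_equal(same@difference, 0)
  expect_equal(same@pValue, 1)
  shifted <- asymmetryContrast(rep(0.1, 12), rep(0.3, 12), nComparisons = 9)
  expect_true(shifted@degenerate)
  expect_equal(shifted@pValue, 0)
  set.seed(2)
  w <- rnorm(12, 0, 0.01); a <- w + 0.2 + rnorm(12, 0, 0.01)
  res <- asymmetryContrast(w, a, nComparisons = 9)
  expect_lt(res@pValue, 0.01)
  expect_equal(res@pValue, min(1, res@pValueRaw * 9))
})
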