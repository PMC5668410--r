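test_that("rotation matrices satisfy the group identities to 1e-12", {
  expect_equal(rotationMatrix(0), diag(2), tolerance = 1e-12)
  expect_equal(drop(rotationMatrix(90) %*% c(1, 0)), c(0, 1),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, -360, 360); b <- runif(1, -360, 360)
    expect_equal(rotationMatrix(a) %*% rotationMatrix(b),
                 rotationMatrix(a + b), tolerance = 1e-12)
    expect_equal(det(rotationMatrix(a)), 1, tolerance = 1e-12)
    expect_equal(rotationMatrix(a) %*% t(rotationMatrix(a)), diag(2),
                 tolerance = 1e-12)
  }
})

test_that("direction labels encode to the expected unit vectors", {
  expect_equal(unname(encodeDirection(0)), cbind(1, 0), tolerance = 1e-12)
  expect_equal(unname(encodeDirection(90)), cbind(0, 1), tolerance = 1e-12)
  expect_equal(unname(encodeDirection(225)),
               cbind(-sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(encodeDirection(seq(0, 315, 45))^2)),
               rep(1, 8), tolerance = 1e-12)
})

test_that("noiseless data is fitted exactly at the true rotation and worse at +180", {
  for (dt in c(0, 45, 90)) {
    cfg <- noiselessConfig(deltaThetaTrue = dt, seed = 40 + dt)
    x <- makeTrials(cfg)
    dec <- fitCommonDecoder(x, dt, lambda = 1e-9)
    expect_lt(aimPredictionError(dec, x), 1e-6)
    opp <- fitCommonDecoder(x, dt + 180, lambda = 1e-9)
    expect_gt(aimPredictionError(opp, x), 0.1)
  }
})

test_that("all-zero features yield a zero weight matrix and intercept predictions", {
  x <- TrialPatterns(matrix(0, 32, 5),
                     direction = rep(seq(0, 315, 45), 4),
                     posture = rep(c("Pro", "Mid"), each = 16),
                     run = rep(1:4, each = 8))
  dec <- fitCommonDecoder(x, 0, lambda = 1)
  expect_equal(max(abs(dec@w)), 0)
  pred <- predictAim(dec, x)
  expect_true(all(abs(sweep(pred, 2, dec@intercept)) < 1e-12))
  expect_error(fitCommonDecoder(x[, posture(x) == "Pro"], 0, lambda = 1),
               "design error")
})

test_that("the stacked ridge solution matches a brute-force least-squares oracle", {
  # tiny instance: 4 features, 16 trials, vanishing regularization
  set.seed(77)
  X <- matrix(rnorm(16 * 4), 16, 4)
  dirs <- rep(seq(0, 315, 45), 2)
  post <- rep(c("Pro", "Mid"), each = 8)
  x <- TrialPatterns(X, direction = dirs, posture = post,
                     run = rep(1:2, each = 8))
  for (dt in c(0, 35, 90)) {
    dec <- fitCommonDecoder(x, dt, lambda = 1e-9)
    U <- encodeDirection(dirs)
    U[post == "Mid", ] <- U[post == "Mid", ] %*% rotationMatrix(dt)
    oracle <- stats::lm.fit(cbind(1, X), U)$coefficients
    expect_equal(unname(dec@w), unname(t(oracle[-1, ])), tolerance = 1e-6)
    expect_equal(unname(dec@intercept), unname(oracle[1, ]), tolerance = 1e-6)
  }
})

test_that("lasso and ridge penalties agree on strongly identified noiseless data", {
  cfg <- noiselessConfig(deltaThetaTrue = 45, nVoxels = 12, seed = 3)
  x <- makeTrials(cfg)
  ridge <- fitCommonDecoder(x, 45, penalty = "ridge", lambda = 1e-6)
  lasso <- fitCommonDecoder(x, 45, penalty = "lasso", lambda = 1e-6)
  expect_lt(aimPredictionError(ridge, x), 1e-6)
  expect_lt(aimPredictionError(lasso, x), 1e-3)
})

test_that("the error curve of noiseless extrinsic data bottoms out at 0 degrees", {
  cfg <- noiselessConfig(deltaThetaTrue = 0, seed = 8)
  x <- makeTrials(cfg)
  est <- errorCurve(x)
  expect_equal(est@deltaThetaHat, 0)
  expect_false(est@uninformative)
  expect_identical(est@grid, seq(-45, 315, by = 5))
})

test_that("the error curve is deterministic and 360-degree periodic", {
  cfg <- noisyConfig(deltaThetaTrue = 30, seed = 51, runsPerPosture = 3)
  x <- makeTrials(cfg, zscore = TRUE)
  e1 <- errorCurve(x, grid = seq(-45, 90, by = 15))
  e2 <- errorCurve(x, grid = seq(-45, 90, by = 15))
  expect_identical(e1@errorCurve, e2@errorCurve)
  per <- errorCurve(x, grid = c(10, 25, 370, 385))
  expect_equal(per@errorCurve[1:2], per@errorCurve[3:4], tolerance = 1e-9)
})

test_that("a 90-degree frame is recovered within one grid step under noise", {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 100,
                         nNeuronsPerVoxel = 10, deltaThetaTrue = 90,
                         noiseSd = 0.3, runsPerPosture = 4, seed = 61)
  x <- makeTrials(cfg, zscore = TRUE)
  est <- errorCurve(x)
  expect_lte(abs(est@deltaThetaHat - 90), 5)
})

test_that("rotating the generative frame by an extra delta shifts the estimate equivariantly", {
  for (extra in c(45, 135)) {
    cfg <- noiselessConfig(deltaThetaTrue = 45 + extra, seed = 70 + extra)
    x <- makeTrials(cfg)
    est <- errorCurve(x)
    expect_lte(abs(est@deltaThetaHat - (45 + extra)) %% 360, 5)
  }
})

test_that("nested cross-validation preconditions and modes are honored", {
  cfg <- noiselessConfig(runsPerPosture = 2, seed = 9)
  x <- makeTrials(cfg)
  expect_error(errorCurve(x), "at least 3 runs")
  full <- errorCurve(x, grid = seq(-45, 315, 45), wFit = "full")
  expect_equal(full@deltaThetaHat, 0)
  cfg3 <- noiselessConfig(deltaThetaTrue = 90, runsPerPosture = 3, seed = 10)
  x3 <- makeTrials(cfg3)
  nested <- errorCurve(x3, fullyNested = TRUE)
  expect_equal(nested@deltaThetaHat, 90)
  expect_equal(nested@deltaThetaHatNested, 90, tolerance = 5)
})

test_that("the lasso error-curve path recovers a noiseless rotation on small data", {
  cfg <- noiselessConfig(deltaThetaTrue = 45, nVoxels = 10, runsPerPosture = 3,
                         seed = 12)
  x <- makeTrials(cfg)
  est <- errorCurve(x, grid = seq(-45, 315, by = 45), penalty = "lasso",
                    lambdas = c(1e-4, 1e-2))
  expect_equal(est@deltaThetaHat, 45)
  expect_identical(est@penalty, "lasso")
})

test_that("coordinate-index readout applies the stated tie-break and flat-curve rules", {
  est <- coordinateIndexEstimate(c(-45, 0, 55, 90), c(0.9, 0.8, 0.2, 0.8))
  expect_equal(estimateCoordinateIndex(est), 55)
  tie <- coordinateIndexEstimate(c(-5, 0, 5), c(0.5, 0.9, 0.5))
  expect_equal(estimateCoordinateIndex(tie), 5)
  tie2 <- coordinateIndexEstimate(c(-10, -5, 5, 10), c(0.5, 0.5, 0.5, 0.6))
  expect_equal(estimateCoordinateIndex(tie2), 5)
  flat <- coordinateIndexEstimate(seq(0, 90, 5), rep(1, 19))
  expect_true(flat@uninformative)
  expect_warning(v <- estimateCoordinateIndex(flat), "uninformative")
  expect_true(is.na(v))
})

test_that("group-level circular statistics summarize and test the indices", {
  allZero <- groupCoordinateIndex(rep(0, 6))
  expect_equal(allZero$summary@meanAngle, 0)
  expect_equal(allZero$summary@ciHalfwidth, 0)
  expect_gt(allZero$tests$pValue[allZero$tests$reference == 0], 0.5)
  set.seed(2)
  rotated <- groupCoordinateIndex(58.8 + rnorm(12, 0, 6))
  expect_lt(rotated$tests$pValue[rotated$tests$reference == 0], 0.001)
  expect_lt(rotated$tests$pValue[rotated$tests$reference == 90], 0.001)
  expect_error(groupCoordinateIndex(c(10, 20)), "size error")
})
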