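# One small rendered run shared by several tests: 2 runs/posture, noiseless.
.renderedFixture <- function(driftPerVolume = 0, baselineLevel = 100) {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 15, nNeuronsPerVoxel = 4,
                         deltaThetaTrue = 45, pdRotationJitterSd = 0,
                         noiseSd = 0, runsPerPosture = 2, seed = 5)
  x <- generateTrials(generatePopulation(cfg, 5), cfg)
  list(cfg = cfg, x = x,
       runs = generateTimeseries(x, cfg, baselineLevel = baselineLevel,
                                 driftPerVolume = driftPerVolume))
}

test_that("a 32-trial run renders to 109 volumes (20 s rest + 32 x 6 s + 6 s)", {
  fx <- .renderedFixture()
  expect_identical(nrow(fx$runs[[1]]@volumes), 109L)
  expect_equal(nrow(fx$runs[[1]]@volumes), (20 + 32 * 6 + 6) / 2)
})

test_that("hemodynamic shift moves the series by exactly delay/TR volumes", {
  fx <- .renderedFixture()
  s <- fx$runs[[1]]
  sh <- shiftHemodynamic(s, 4)
  expect_identical(nrow(sh@volumes), nrow(s@volumes) - 2L)
  expect_equal(sh@volumes[1, ], s@volumes[3, ])
  expect_identical(shiftHemodynamic(s, 0), s)
  expect_error(shiftHemodynamic(s, 3), "multiple of the TR")
})

test_that("baseline normalization maps a constant series to ones and scales task values", {
  vol <- matrix(5, nrow = 20, ncol = 3)
  s <- new("RunSeries", volumes = vol, trSeconds = 2, restOnsetSeconds = 20,
           blockDurationSeconds = 6, blockOnsets = 20, direction = 0,
           posture = "Pro", runId = 1L, participantId = 1L)
  expect_true(all(normalizeBaseline(s)@volumes == 1))
  vol2 <- rbind(matrix(2, 10, 1), matrix(3, 10, 1))
  s2 <- new("RunSeries", volumes = vol2, trSeconds = 2, restOnsetSeconds = 20,
            blockDurationSeconds = 6, blockOnsets = 20, direction = 0,
            posture = "Pro", runId = 1L, participantId = 1L)
  expect_equal(normalizeBaseline(s2)@volumes[15, 1], 1.5)
  # scale equivariance: input * c gives identical output
  s3 <- s2; s3@volumes <- s2@volumes * 7.3
  expect_equal(normalizeBaseline(s3)@volumes, normalizeBaseline(s2)@volumes)
  # degenerate baseline names the voxel
  s4 <- s2; s4@volumes[1:10, 1] <- 0
  expect_error(normalizeBaseline(s4), "voxel 1")
})

test_that("detrending removes a pure line and is idempotent", {
  t <- seq_len(40)
  vol <- cbind(2 + 0.5 * t, -1 + 0.1 * t)
  s <- new("RunSeries", volumes = vol, trSeconds = 2, restOnsetSeconds = 20,
           blockDurationSeconds = 6, blockOnsets = c(20, 26, 32, 38),
           direction = c(0, 90, 180, 270), posture = "Pro", runId = 1L,
           participantId = 1L)
  for (m in c("rest", "all")) {
    d <- detrendLinear(s, method = m)
    # slope gone, run mean preserved
    expect_lt(max(abs(apply(d@volumes, 2, function(y)
      stats::coef(stats::lm(y ~ t))[2]))), 1e-10)
    expect_equal(colMeans(d@volumes), colMeans(vol))
    d2 <- detrendLinear(d, method = m)
    expect_equal(d2@volumes, d@volumes, tolerance = 1e-10)
  }
  expect_error(detrendLinear(new("RunSeries", volumes = vol[1:2, , drop = FALSE],
                                 trSeconds = 2, restOnsetSeconds = 2,
                                 blockDurationSeconds = 2, blockOnsets = 2,
                                 direction = 0, posture = "Pro", runId = 1L,
                                 participantId = 1L)), "size error")
})

test_that("detrending white noise leaves a residual slope within 3 standard errors", {
  set.seed(8)
  vol <- matrix(rnorm(120 * 4), 120, 4)
  s <- new("RunSeries", volumes = vol, trSeconds = 2, restOnsetSeconds = 20,
           blockDurationSeconds = 6, blockOnsets = 20 + 6 * (0:15),
           direction = rep(seq(0, 315, 45), 2), posture = "Pro", runId = 1L,
           participantId = 1L)
  d <- detrendLinear(s, method = "all")
  t <- seq_len(120)
  for (v in 1:4) {
    fit <- summary(stats::lm(d@volumes[, v] ~ t))$coefficients
    expect_lt(abs(fit[2, 1]), 3 * fit[2, 2])
  }
})

test_that("per-sample z-scoring matches the two-point closed form and flags constants", {
  x <- TrialPatterns(rbind(c(1, 3), c(4, 4)), direction = c(0, 45),
                     posture = "Pro", run = c(1, 1))
  expect_warning(z <- zscorePatterns(x), "zero-variance")
  Z <- responses(z)
  expect_equal(Z[1, ], c(v0001 = -1 / sqrt(2), v0002 = 1 / sqrt(2)))
  expect_equal(unname(Z[2, ]), c(0, 0))
  expect_identical(S4Vectors::metadata(z)$zeroVarianceSamples, 2L)
})

test_that("z-scored rows have mean 0 and unit sd", {
  cfg <- noisyConfig(seed = 14)
  z <- makeTrials(cfg, zscore = TRUE)
  Z <- responses(z)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_equal(apply(Z, 1, stats::sd), rep(1, nrow(Z)), tolerance = 1e-12)
})

test_that("extraction yields 3 samples per block per volume, or 1 per trial", {
  fx <- .renderedFixture()
  sh <- shiftHemodynamic(fx$runs[[1]], 4)
  pv <- extractTrialPatterns(sh, mode = "volume")
  expect_identical(nrow(responses(pv)), 96L)
  pt <- extractTrialPatterns(sh, mode = "trial")
  expect_identical(nrow(responses(pt)), 32L)
  expect_identical(aimDirection(pt), fx$runs[[1]]@direction)
  # unshifted series: final block runs past a truncated run
  tr <- fx$runs[[1]]
  tr@volumes <- tr@volumes[1:100, ]
  expect_error(extractTrialPatterns(tr), "boundary error")
})

test_that("the noiseless pipeline round-trips trial patterns (zero and nonzero drift)", {
  for (drift in c(0, 0.01)) {
    fx <- .renderedFixture(driftPerVolume = drift)
    rec <- preprocessRuns(fx$runs, mode = "trial", zscore = FALSE)
    expect_identical(aimDirection(rec), aimDirection(fx$x))
    restMean <- 100 + drift * 6.5  # rest volumes 3..12 of the original series
    P0 <- responses(fx$x)
    P1 <- responses(rec) * restMean
    dif <- (P0 - mean(P0)) - (P1 - mean(P1))
    expect_lt(max(abs(dif)) / max(abs(P0 - mean(P0))), 1e-6)
  }
})

test_that("preprocessing then z-scoring equals z-scoring the generator patterns", {
  fx <- .renderedFixture(driftPerVolume = 0.005)
  rec <- preprocessRuns(fx$runs, mode = "trial", zscore = TRUE)
  zx <- zscorePatterns(fx$x)
  expect_equal(unname(responses(rec)), unname(responses(zx)), tolerance = 1e-6)
})
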