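test_that("configuration invariants are enforced with informative errors", {
  expect_error(syntheticConfig(trialsPerRun = 30), "divisible")
  expect_error(syntheticConfig(noiseSd = -1), "noiseSd")
  expect_error(syntheticConfig(nVoxels = 0), "nVoxels")
  expect_s4_class(syntheticConfig(), "SyntheticConfig")
})

test_that("degenerate single-unit population has a 1x1 weight matrix summing to 1", {
  cfg <- syntheticConfig(nVoxels = 1, nNeuronsPerVoxel = 1)
  pop <- generatePopulation(cfg, participantSeed = 5)
  expect_identical(dim(pop@weights), c(1L, 1L))
  expect_equal(sum(pop@weights), 1)
  expect_length(pop@pd, 1L)
})

test_that("population generation is deterministic and respects ranges", {
  cfg <- syntheticConfig(nVoxels = 10, nNeuronsPerVoxel = 4,
                         tuningAmplitudeRange = c(0.5, 1.5),
                         baselineRange = c(1, 3))
  p1 <- generatePopulation(cfg, 42)
  p2 <- generatePopulation(cfg, 42)
  expect_identical(p1@pd, p2@pd)
  expect_identical(p1@weights, p2@weights)
  expect_true(all(p1@pd >= 0 & p1@pd < 360))
  expect_true(all(p1@amplitude >= 0.5 & p1@amplitude <= 1.5))
  expect_true(all(p1@baseline >= 1 & p1@baseline <= 3))
  expect_equal(rowSums(p1@weights), rep(1, 10))
})

test_that("pooled preferred directions are uniform on the circle", {
  cfg <- syntheticConfig(nVoxels = 50, nNeuronsPerVoxel = 20)
  pass <- 0L
  resultants <- numeric(100)
  for (s in 1:100) {
    pd <- generatePopulation(cfg, s)@pd
    resultants[s] <- sqrt(mean(cos(pd * pi / 180))^2 +
                            mean(sin(pd * pi / 180))^2)
    if (rayleighP(pd) > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
  expect_lt(stats::median(resultants), 0.1)
})

test_that("zero rotation with zero noise gives identical Pro and Mid responses per label", {
  cfg <- noiselessConfig(deltaThetaTrue = 0)
  x <- makeTrials(cfg)
  X <- responses(x)
  for (d in seq(0, 315, by = 45)) {
    pro <- X[posture(x) == "Pro" & aimDirection(x) == d, , drop = FALSE]
    mid <- X[posture(x) == "Mid" & aimDirection(x) == d, , drop = FALSE]
    expect_equal(pro[1, ], mid[1, ], tolerance = 1e-12)
  }
})

test_that("a 90-degree frame rotation maps the Mid response at 90 to the Pro response at 0", {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 1, nNeuronsPerVoxel = 1,
                         deltaThetaTrue = 90, pdRotationJitterSd = 0,
                         noiseSd = 0, runsPerPosture = 1, seed = 7)
  pop <- generatePopulation(cfg, 7)
  pop@pd <- 0  # single unit with PD at 0 degrees
  x <- generateTrials(pop, cfg)
  X <- responses(x)
  rMid90 <- X[posture(x) == "Mid" & aimDirection(x) == 90, 1]
  rPro0 <- X[posture(x) == "Pro" & aimDirection(x) == 0, 1]
  expect_equal(unname(rMid90), unname(rPro0), tolerance = 1e-12)
})

test_that("the Mid response matrix equals Pro with labels remapped by -deltaThetaTrue", {
  for (dt in c(45, 90, 135)) {
    cfg <- noiselessConfig(deltaThetaTrue = dt, seed = dt)
    x <- makeTrials(cfg)
    X <- responses(x)
    for (d in c(0, 90, 225)) {
      mid <- X[posture(x) == "Mid" & aimDirection(x) == d, , drop = FALSE]
      pro <- X[posture(x) == "Pro" &
                 aimDirection(x) == (d - dt) %% 360, , drop = FALSE]
      expect_equal(mid[1, ], pro[1, ], tolerance = 1e-12)
    }
  }
})

test_that("trial design bookkeeping: size, run structure, and label balance", {
  cfg <- syntheticConfig(nParticipants = 1, nVoxels = 10, nNeuronsPerVoxel = 3,
                         runsPerPosture = 3, trialsPerRun = 16, seed = 1)
  x <- makeTrials(cfg)
  expect_identical(nrow(responses(x)), 2L * 3L * 16L)
  tab <- table(runId(x), aimDirection(x))
  expect_true(all(tab == 16 / 8))
  expect_identical(sort(unique(runId(x))), 1:6)
  byRun <- table(runId(x), posture(x))
  expect_true(all(byRun[1:3, "Pro"] == 16))
  expect_true(all(byRun[4:6, "Mid"] == 16))
})

test_that("trial generation is deterministic under a fixed seed", {
  cfg <- noisyConfig(seed = 33)
  pop <- generatePopulation(cfg, 33)
  x1 <- generateTrials(pop, cfg, seed = 99)
  x2 <- generateTrials(pop, cfg, seed = 99)
  expect_identical(responses(x1), responses(x2))
  expect_identical(aimDirection(x1), aimDirection(x2))
})

test_that("mismatched population and config sizes raise a size error", {
  cfg <- noiselessConfig()
  pop <- generatePopulation(cfg, 1)
  expect_error(generateTrials(pop, syntheticConfig(nVoxels = 5)), "size error")
})

test_that("noiseless EMG with zero shift gives identical Pro and Mid tables", {
  emg <- generateEmg(truePdPro = 120, pdShift = 0, noiseSd = 0)
  pro <- emg[emg$posture == "Pro", ]
  mid <- emg[emg$posture == "Mid", ]
  expect_equal(pro$activation, mid$activation)
})

test_that("noiseless EMG evaluates the cosine tuning model exactly", {
  emg <- generateEmg(truePdPro = 0, pdShift = 0, amplitude = 1, baseline = 2,
                     noiseSd = 0, nTrials = 1)
  pro <- emg[emg$posture == "Pro", ]
  expect_equal(pro$activation[pro$direction_deg == 0], 3)
  expect_equal(pro$activation[pro$direction_deg == 180], 1)
})

test_that("EMG generator validates its arguments", {
  expect_error(generateEmg(0, noiseSd = -0.1), "noiseSd")
  expect_error(generateEmg(0, nTrials = 0), "nTrials")
})
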