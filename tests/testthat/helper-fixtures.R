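# Small deterministic fixtures used across the suite.

# A compact noiseless study configuration: exact linear structure, fast.
noiselessConfig <- function(deltaThetaTrue = 0, nVoxels = 30,
                            runsPerPosture = 3, seed = 11) {
  syntheticConfig(nParticipants = 1, nVoxels = nVoxels, nNeuronsPerVoxel = 5,
                  deltaThetaTrue = deltaThetaTrue, pdRotationJitterSd = 0,
                  noiseSd = 0, runsPerPosture = runsPerPosture, seed = seed)
}

# A small noisy configuration for stochastic checks.
noisyConfig <- function(deltaThetaTrue = 0, noiseSd = 0.3, nVoxels = 60,
                        runsPerPosture = 4, seed = 21) {
  syntheticConfig(nParticipants = 1, nVoxels = nVoxels, nNeuronsPerVoxel = 8,
                  deltaThetaTrue = deltaThetaTrue, noiseSd = noiseSd,
                  runsPerPosture = runsPerPosture, seed = seed)
}

makeTrials <- function(cfg, participantSeed = cfg@seed + 1,
                       trialSeed = cfg@seed + 2, zscore = FALSE) {
  x <- generateTrials(generatePopulation(cfg, participantSeed), cfg,
                      seed = trialSeed)
  if (zscore) zscorePatterns(x) else x
}

# Independent brute-force mean direction: explicit loop over the angles.
bruteCircularMean <- function(angles) {
  C <- 0; S <- 0
  for (a in angles) {
    C <- C + cos(a * pi / 180)
    S <- S + sin(a * pi / 180)
  }
  (atan2(S, C) * 180 / pi) %% 360
}

# Independent cosine-fit oracle: global grid search over mu (0.1 degree),
# refined to 0.01 degree; k and b solved in closed form at fixed mu.
gridSearchCosine <- function(directions, responses) {
  rssAt <- function(mu) {
    X <- cbind(cos((directions - mu) * pi / 180), 1)
    fit <- stats::lm.fit(X, responses)
    sum(fit$residuals^2)
  }
  coarse <- seq(0, 359.9, by = 0.1)
  r1 <- vapply(coarse, rssAt, numeric(1))
  best <- coarse[which.min(r1)]
  fine <- seq(best - 0.1, best + 0.1, by = 0.01)
  r2 <- vapply(fine, rssAt, numeric(1))
  fine[which.min(r2)] %% 360
}

# Rayleigh uniformity p-value (large-sample approximation).
rayleighP <- function(angles) {
  n <- length(angles)
  R <- sqrt(mean(cos(angles * pi / 180))^2 + mean(sin(angles * pi / 180))^2)
  Z <- n * R^2
  exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
}
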