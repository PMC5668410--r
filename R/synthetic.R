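#' Create a synthetic-generator configuration
#'
#' Defaults reproduce the study design the analysis assumes: 12 participants,
#' 8 runs per posture of 32 trials each (8 directions x 4 repetitions,
#' randomized order per run), cosine-tuned units pooled 20-per-voxel into 200
#' voxels, a per-unit rotation jitter of 10 degrees around the ground-truth
#' frame rotation, and additive Gaussian trial noise.
#'
#' @param nParticipants,nVoxels,nNeuronsPerVoxel,runsPerPosture,trialsPerRun,nDirections
#'   design counts; see \linkS4class{SyntheticConfig}.
#' @param deltaThetaTrue ground-truth frame rotation from Pro to Mid, degrees.
#' @param pdRotationJitterSd per-unit sd of the rotation, degrees.
#' @param tuningAmplitudeRange,baselineRange uniform ranges for unit tuning
#'   amplitude and baseline.
#' @param noiseSd additive Gaussian noise sd per trial and voxel.
#' @param seed master seed.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' syntheticConfig(nParticipants = 2, deltaThetaTrue = 90)
#' @export
syntheticConfig <- function(nParticipants = 12L, nVoxels = 200L,
                            nNeuronsPerVoxel = 20L, deltaThetaTrue = 0,
                            pdRotationJitterSd = 10,
                            tuningAmplitudeRange = c(0.5, 1.5),
                            baselineRange = c(1, 3), noiseSd = 0.3,
                            runsPerPosture = 8L, trialsPerRun = 32L,
                            nDirections = 8L, seed = 1L) {
  new("SyntheticConfig",
      nParticipants = as.integer(nParticipants),
      nVoxels = as.integer(nVoxels),
      nNeuronsPerVoxel = as.integer(nNeuronsPerVoxel),
      deltaThetaTrue = as.numeric(deltaThetaTrue),
      pdRotationJitterSd = as.numeric(pdRotationJitterSd),
      tuningAmplitudeRange = as.numeric(tuningAmplitudeRange),
      baselineRange = as.numeric(baselineRange),
      noiseSd = as.numeric(noiseSd),
      runsPerPosture = as.integer(runsPerPosture),
      trialsPerRun = as.integer(trialsPerRun),
      nDirections = as.integer(nDirections),
      seed = as.integer(seed))
}

#' Draw a cosine-tuned unit population for one participant
#'
#' Unit preferred directions are uniform on the circle; amplitudes and
#' baselines are uniform within their configured ranges. Each voxel pools its
#' own block of \code{nNeuronsPerVoxel} units with nonnegative weights
#' normalized to sum to 1, so every voxel's expected response scale is
#' comparable.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param participantSeed integer seed for this participant's draws.
#' @return A \linkS4class{NeuronPopulation}.
#' @examples
#' pop <- generatePopulation(syntheticConfig(nVoxels = 4), participantSeed = 7)
#' rowSums(pop@weights)
#' @export
generatePopulation <- function(config, participantSeed = config@seed) {
  validObject(config)
  nv <- config@nVoxels
  m <- config@nNeuronsPerVoxel
  nu <- nv * m
  .withSeed(participantSeed, {
    pd <- stats::runif(nu, 0, 360)
    amp <- stats::runif(nu, config@tuningAmplitudeRange[1],
                        config@tuningAmplitudeRange[2])
    base <- stats::runif(nu, config@baselineRange[1], config@baselineRange[2])
    raw <- stats::runif(nu)
    blockSums <- colSums(matrix(raw, nrow = m))
    W <- matrix(0, nrow = nv, ncol = nu)
    W[cbind(rep(seq_len(nv), each = m), seq_len(nu))] <- raw / rep(blockSums, each = m)
    new("NeuronPopulation", pd = pd, amplitude = amp, baseline = base,
        weights = W)
  })
}

# Voxel-level cosine coefficients [a | c | s] for unit PDs phi:
# voxel response to direction theta is a + c*cos(theta) + s*sin(theta).
.voxelCoefficients <- function(population, phi) {
  U <- cbind(population@baseline,
             population@amplitude * .cosd(phi),
             population@amplitude * .sind(phi))
  population@weights %*% U
}

#' Generate the two-posture trial dataset for one participant
#'
#' For a Pro trial at direction theta every unit responds
#' \eqn{b + k\cos(\theta - \phi)}; for a Mid trial the unit's preferred
#' direction is first rotated by the ground-truth frame rotation plus
#' unit-specific jitter (in task-label units, where the positive rotation is
#' the direction in which the empirical muscle rotation is reported). Voxel
#' responses are the weighted unit mixture plus i.i.d. Gaussian noise. Trials
#' are organized into runs with a randomized direction order per run; every
#' direction appears \code{trialsPerRun / nDirections} times per run. Run ids
#' are 1..R for Pro and R+1..2R for Mid. Direction labels are always the
#' task-frame (extrinsic) labels.
#'
#' @param population a \linkS4class{NeuronPopulation}.
#' @param config a \linkS4class{SyntheticConfig} consistent with the
#'   population's sizes.
#' @param participant integer participant id recorded in the output.
#' @param seed seed for jitter, trial orders and noise; defaults to the
#'   config seed.
#' @return A \linkS4class{TrialPatterns} with
#'   \code{2 * runsPerPosture * trialsPerRun} samples.
#' @examples
#' cfg <- syntheticConfig(nVoxels = 10, nNeuronsPerVoxel = 4,
#'                        runsPerPosture = 2, trialsPerRun = 8)
#' x <- generateTrials(generatePopulation(cfg), cfg)
#' table(posture(x), aimDirection(x))
#' @export
generateTrials <- function(population, config, participant = 1L,
                           seed = config@seed) {
  validObject(config)
  if (nrow(population@weights) != config@nVoxels ||
      length(population@pd) != config@nVoxels * config@nNeuronsPerVoxel)
    .stopf("size error: population (%d voxels x %d units) does not match config",
           nrow(population@weights), length(population@pd))
  nv <- config@nVoxels
  R <- config@runsPerPosture
  tpr <- config@trialsPerRun
  nd <- config@nDirections
  dirs <- seq(0, 360 - 360 / nd, by = 360 / nd)
  reps <- tpr %/% nd
  nTot <- 2L * R * tpr

  .withSeed(seed, {
    jitter <- stats::rnorm(length(population@pd), 0, config@pdRotationJitterSd)
    coefPro <- .voxelCoefficients(population, population@pd)
    coefMid <- .voxelCoefficients(population,
                                  population@pd + config@deltaThetaTrue + jitter)
    direction <- numeric(nTot)
    post <- character(nTot)
    run <- integer(nTot)
    resp <- matrix(0, nrow = nTot, ncol = nv)
    i <- 0L
    for (p in c("Pro", "Mid")) {
      coef <- if (p == "Pro") coefPro else coefMid
      for (r in seq_len(R)) {
        th <- sample(rep(dirs, each = reps))
        D <- cbind(1, .cosd(th), .sind(th))
        rows <- i + seq_len(tpr)
        resp[rows, ] <- D %*% t(coef)
        direction[rows] <- th
        post[rows] <- p
        run[rows] <- if (p == "Pro") r else R + r
        i <- i + tpr
      }
    }
    if (config@noiseSd > 0)
      resp <- resp + matrix(stats::rnorm(nTot * nv, 0, config@noiseSd),
                            nrow = nTot)
    TrialPatterns(resp, direction = direction, posture = post, run = run,
                  participant = participant)
  })
}

#' Simulate the full multi-participant study
#'
#' Draws an independent unit population and trial dataset per participant,
#' with per-participant sub-seeds derived deterministically from the config
#' seed, and returns one \linkS4class{TrialPatterns} per participant.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A list of \linkS4class{TrialPatterns}, length
#'   \code{nParticipants}.
#' @export
simulateStudy <- function(config) {
  validObject(config)
  lapply(seq_len(config@nParticipants), function(p) {
    pop <- generatePopulation(config, .derivedSeed(config@seed, p, 1L))
    generateTrials(pop, config, participant = p,
                   seed = .derivedSeed(config@seed, p, 2L))
  })
}

#' Generate a synthetic EMG tuning dataset
#'
#' Trial-mean activations of directionally tuned muscles under the two
#' postures. Pro-posture means follow \eqn{k\cos(\theta-\mu)+b} with
#' \eqn{\mu} the muscle's true preferred direction; under Mid the preferred
#' direction is shifted clockwise by \code{pdShift}
#' (\eqn{\mu_{Mid} = \mu_{Pro} - \mathrm{pdShift}}), matching the convention
#' in which the reported muscle rotation is positive. Gaussian noise is added
#' per trial.
#'
#' @param truePdPro numeric vector, Pro-posture preferred direction per
#'   muscle (degrees).
#' @param pdShift clockwise PD shift per muscle (degrees; recycled).
#' @param amplitude,baseline tuning amplitude and offset (recycled).
#' @param noiseSd trial noise sd; must be >= 0.
#' @param nTrials trials per direction and posture (>= 1).
#' @param directions aiming directions, degrees.
#' @param muscleIds labels, default M1..Mk.
#' @param seed RNG seed.
#' @return A data.frame with columns muscle_id, posture, direction_deg,
#'   trial, activation.
#' @examples
#' emg <- generateEmg(truePdPro = 120, pdShift = 58.8, noiseSd = 0)
#' head(emg)
#' @export
generateEmg <- function(truePdPro, pdShift = 58.8, amplitude = 1, baseline = 2,
                        noiseSd = 0.1, nTrials = 10L,
                        directions = seq(0, 315, by = 45),
                        muscleIds = NULL, seed = 1L) {
  if (noiseSd < 0) .stopf("configuration error: 'noiseSd' must be >= 0")
  if (nTrials < 1L) .stopf("configuration error: 'nTrials' must be >= 1")
  nm <- length(truePdPro)
  pdShift <- rep_len(pdShift, nm)
  amplitude <- rep_len(amplitude, nm)
  baseline <- rep_len(baseline, nm)
  if (is.null(muscleIds)) muscleIds <- sprintf("M%d", seq_len(nm))
  grid <- expand.grid(trial = seq_len(nTrials), direction_deg = directions,
                      posture = c("Pro", "Mid"), muscle = seq_len(nm),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(grid$posture == "Pro", truePdPro[grid$muscle],
               truePdPro[grid$muscle] - pdShift[grid$muscle])
  mean_act <- baseline[grid$muscle] +
    amplitude[grid$muscle] * .cosd(grid$direction_deg - mu)
  act <- .withSeed(seed, mean_act +
                     if (noiseSd > 0) stats::rnorm(nrow(grid), 0, noiseSd) else 0)
  data.frame(muscle_id = muscleIds[grid$muscle], posture = grid$posture,
             direction_deg = grid$direction_deg, trial = grid$trial,
             activation = act, stringsAsFactors = FALSE)
}

#' Render a trial dataset as per-run volume time series
#'
#' Each run becomes a TR-resolution series: an initial rest period at a
#' configurable baseline level plus an optional linear drift, then one
#' fixed-duration block per trial whose pattern enters the signal delayed by
#' the hemodynamic lag, then a short terminal rest that absorbs the delayed
#' tail of the last block. This is the inverse of the signal-conditioning
#' pipeline up to noise: shifting, baseline normalization, rest-based
#' detrending and extraction recover the trial patterns up to the baseline
#' normalization constant.
#'
#' @param dataset a \linkS4class{TrialPatterns} for a single participant.
#' @param config the \linkS4class{SyntheticConfig} used to generate it (for
#'   the run design).
#' @param baselineLevel signal level during rest (arbitrary units).
#' @param driftPerVolume linear drift added per volume.
#' @param delaySeconds hemodynamic delay applied to block responses.
#' @param trSeconds sampling interval.
#' @param restOnsetSeconds initial rest duration.
#' @param blockSeconds task block duration.
#' @param restEndSeconds terminal rest duration.
#' @param noiseSd additive volume noise sd (0 = noiseless rendering).
#' @param seed RNG seed for volume noise.
#' @return A list of \linkS4class{RunSeries}, one per run.
#' @export
generateTimeseries <- function(dataset, config, baselineLevel = 100,
                               driftPerVolume = 0, delaySeconds = 4,
                               trSeconds = 2, restOnsetSeconds = 20,
                               blockSeconds = 6, restEndSeconds = 6,
                               noiseSd = 0, seed = config@seed) {
  stopifnot(is(dataset, "TrialPatterns"))
  if (length(unique(participantId(dataset))) != 1L)
    .stopf("generateTimeseries expects a single participant's dataset")
  if (delaySeconds %% trSeconds != 0)
    .stopf("configuration error: 'delaySeconds' must be a multiple of the TR")
  volPerBlock <- blockSeconds / trSeconds
  restVol <- restOnsetSeconds / trSeconds
  delayVol <- delaySeconds / trSeconds
  runs <- sort(unique(runId(dataset)))
  X <- .featMatrix(dataset)
  out <- vector("list", length(runs))
  k <- 0L
  for (r in runs) {
    sel <- which(runId(dataset) == r)
    nb <- length(sel)
    nVol <- restVol + nb * volPerBlock + restEndSeconds / trSeconds
    vol <- matrix(baselineLevel, nrow = nVol, ncol = ncol(X)) +
      driftPerVolume * (seq_len(nVol) - 1)
    for (j in seq_len(nb)) {
      v0 <- restVol + (j - 1L) * volPerBlock + delayVol
      rows <- (v0 + 1L):(v0 + volPerBlock)
      vol[rows, ] <- vol[rows, ] + rep(X[sel[j], ], each = volPerBlock)
    }
    if (noiseSd > 0)
      vol <- vol + .withSeed(.derivedSeed(seed, r, 3L),
                             matrix(stats::rnorm(length(vol), 0, noiseSd),
                                    nrow = nVol))
    k <- k + 1L
    out[[k]] <- new("RunSeries", volumes = vol, trSeconds = trSeconds,
                    restOnsetSeconds = restOnsetSeconds,
                    blockDurationSeconds = blockSeconds,
                    blockOnsets = restOnsetSeconds +
                      (seq_len(nb) - 1) * blockSeconds,
                    direction = aimDirection(dataset)[sel],
                    posture = posture(dataset)[sel][1],
                    runId = as.integer(r),
                    participantId = as.integer(participantId(dataset)[sel][1]))
  }
  out
}
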