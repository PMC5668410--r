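#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
NULL

# ---------------------------------------------------------------------------
# SyntheticConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic population-code generator
#'
#' Holds every generative parameter of the simulated two-posture aiming
#' experiment: population size and tuning ranges, the ground-truth frame
#' rotation between the pronated (Pro) and midway (Mid) postures, trial noise,
#' and the run design (runs per posture, trials per run, number of aiming
#' directions).
#'
#' @slot nParticipants number of simulated participants.
#' @slot nVoxels number of voxels (features) per participant.
#' @slot nNeuronsPerVoxel number of cosine-tuned units pooled into each voxel.
#' @slot deltaThetaTrue degrees; ground-truth rotation of the population's
#'   preferred directions from Pro to Mid (0 = extrinsic frame, 90 =
#'   joint-like frame). Positive values follow the task-label convention in
#'   which the empirically reported muscle rotation is positive.
#' @slot pdRotationJitterSd degrees; per-unit spread of the rotation around
#'   \code{deltaThetaTrue}.
#' @slot tuningAmplitudeRange length-2 numeric; uniform range of unit tuning
#'   amplitudes (response units).
#' @slot baselineRange length-2 numeric; uniform range of unit baselines.
#' @slot noiseSd additive Gaussian noise per trial and voxel (response units).
#' @slot runsPerPosture number of runs per posture.
#' @slot trialsPerRun trials per run; must be divisible by \code{nDirections}.
#' @slot nDirections number of aiming directions (8, spaced 45 degrees).
#' @slot seed integer master seed for all stochastic stages.
#' @export
setClass("SyntheticConfig",
  representation(
    nParticipants = "integer",
    nVoxels = "integer",
    nNeuronsPerVoxel = "integer",
    deltaThetaTrue = "numeric",
    pdRotationJitterSd = "numeric",
    tuningAmplitudeRange = "numeric",
    baselineRange = "numeric",
    noiseSd = "numeric",
    runsPerPosture = "integer",
    trialsPerRun = "integer",
    nDirections = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  counts <- c(
    nParticipants = object@nParticipants,
    nVoxels = object@nVoxels,
    nNeuronsPerVoxel = object@nNeuronsPerVoxel,
    runsPerPosture = object@runsPerPosture,
    trialsPerRun = object@trialsPerRun,
    nDirections = object@nDirections
  )
  for (nm in names(counts)) {
    if (length(counts[[nm]]) != 1L || is.na(counts[[nm]]) || counts[[nm]] < 1L)
      return(sprintf("configuration error: '%s' must be a count >= 1", nm))
  }
  if (object@trialsPerRun %% object@nDirections != 0L)
    return("configuration error: 'trialsPerRun' must be divisible by 'nDirections'")
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) || object@noiseSd < 0)
    return("configuration error: 'noiseSd' must be >= 0")
  if (length(object@pdRotationJitterSd) != 1L || is.na(object@pdRotationJitterSd) ||
      object@pdRotationJitterSd < 0)
    return("configuration error: 'pdRotationJitterSd' must be >= 0")
  for (nm in c("tuningAmplitudeRange", "baselineRange")) {
    rng <- slot(object, nm)
    if (length(rng) != 2L || any(is.na(rng)) || rng[2] < rng[1])
      return(sprintf("configuration error: '%s' must be a nondecreasing pair", nm))
  }
  if (length(object@deltaThetaTrue) != 1L || !is.finite(object@deltaThetaTrue))
    return("configuration error: 'deltaThetaTrue' must be a finite angle")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("configuration error: 'seed' must be a single integer")
  TRUE
})

# ---------------------------------------------------------------------------
# NeuronPopulation
# ---------------------------------------------------------------------------

#' A cosine-tuned unit population with voxel mixing weights
#'
#' Each unit has a preferred direction (degrees, Pro posture), a tuning
#' amplitude and a baseline; voxels observe a nonnegative, row-normalized
#' mixture of the units assigned to them.
#'
#' @slot pd per-unit preferred direction in [0, 360).
#' @slot amplitude per-unit tuning amplitude k (response units).
#' @slot baseline per-unit baseline b (response units).
#' @slot weights voxels x units nonnegative mixing matrix, rows sum to 1.
#' @export
setClass("NeuronPopulation",
  representation(
    pd = "numeric",
    amplitude = "numeric",
    baseline = "numeric",
    weights = "matrix"
  )
)

setValidity("NeuronPopulation", function(object) {
  nu <- length(object@pd)
  if (length(object@amplitude) != nu || length(object@baseline) != nu)
    return("pd, amplitude and baseline must have equal length")
  if (any(object@pd < 0 | object@pd >= 360))
    return("preferred directions must lie in [0, 360)")
  if (ncol(object@weights) != nu)
    return("weights must have one column per unit")
  if (any(object@weights < 0))
    return("mixing weights must be nonnegative")
  if (any(rowSums(object@weights) == 0))
    return("every voxel needs at least one nonzero mixing weight")
  TRUE
})

# ---------------------------------------------------------------------------
# TrialPatterns
# ---------------------------------------------------------------------------

#' Trial-by-feature response patterns with task metadata
#'
#' A \linkS4class{SummarizedExperiment} whose assay holds one column per
#' sample (trial or task volume) and one row per feature (voxel or channel).
#' Column metadata carries the aiming-direction label (degrees on the task's
#' 45-degree lattice), the posture condition ("Pro" or "Mid"), the run id and
#' the participant id.
#'
#' @export
setClass("TrialPatterns", contains = "SummarizedExperiment")

setValidity("TrialPatterns", function(object) {
  cd <- colData(object)
  need <- c("direction_deg", "posture", "run_id", "participant_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s", paste(miss, collapse = ", ")))
  if (!all(cd$posture %in% c("Pro", "Mid")))
    return("posture must be 'Pro' or 'Mid'")
  if (any(!is.finite(cd$direction_deg)) ||
      any(cd$direction_deg < 0 | cd$direction_deg >= 360))
    return("direction_deg must be finite and lie in [0, 360)")
  TRUE
})

# ---------------------------------------------------------------------------
# RunSeries
# ---------------------------------------------------------------------------

#' A single run of volume-by-voxel time series with block timing
#'
#' Emulates one acquisition run: an initial rest period, one fixed-duration
#' task block per trial, and a short terminal rest. Used by the
#' signal-conditioning pipeline (hemodynamic shift, baseline normalization,
#' detrending, trial-pattern extraction).
#'
#' @slot volumes time x voxels matrix.
#' @slot trSeconds sampling interval (seconds per volume).
#' @slot restOnsetSeconds duration of the initial rest period.
#' @slot blockDurationSeconds duration of each task block.
#' @slot blockOnsets onset (seconds from run start) of each block.
#' @slot direction aiming label (degrees) of each block.
#' @slot posture "Pro" or "Mid".
#' @slot runId,participantId integer identifiers.
#' @export
setClass("RunSeries",
  representation(
    volumes = "matrix",
    trSeconds = "numeric",
    restOnsetSeconds = "numeric",
    blockDurationSeconds = "numeric",
    blockOnsets = "numeric",
    direction = "numeric",
    posture = "character",
    runId = "integer",
    participantId = "integer"
  )
)

setValidity("RunSeries", function(object) {
  if (!all(is.finite(object@volumes)))
    return("volumes must be finite")
  if (length(object@blockOnsets) != length(object@direction))
    return("one onset per block is required")
  dur <- nrow(object@volumes) * object@trSeconds
  if (any(object@blockOnsets < 0 |
          object@blockOnsets + object@blockDurationSeconds > dur))
    return("block onsets must fall within the series")
  if (!object@posture %in% c("Pro", "Mid"))
    return("posture must be 'Pro' or 'Mid'")
  TRUE
})

# ---------------------------------------------------------------------------
# CosineFit
# ---------------------------------------------------------------------------

#' A fitted cosine tuning function
#'
#' Parameters of the directional tuning model
#' \eqn{f(\theta) = k \cos(\theta - \mu) + b}: amplitude \code{k} (forced
#' nonnegative by absorbing the sign into \code{mu}), preferred direction
#' \code{mu} in [0, 360) degrees, and offset \code{b}. When the fitted
#' amplitude is numerically zero the fit is flagged untuned and \code{mu} is
#' \code{NA}.
#'
#' @slot k amplitude (response units, >= 0).
#' @slot mu preferred direction in degrees, or NA when untuned.
#' @slot b offset (response units).
#' @slot rss residual sum of squares.
#' @slot n number of samples used.
#' @slot untuned logical flag.
#' @export
setClass("CosineFit",
  representation(k = "numeric", mu = "numeric", b = "numeric",
                 rss = "numeric", n = "integer", untuned = "logical")
)

setValidity("CosineFit", function(object) {
  if (object@k < 0) return("k must be >= 0")
  if (!object@untuned && (is.na(object@mu) || object@mu < 0 || object@mu >= 360))
    return("mu must lie in [0, 360) for tuned fits")
  TRUE
})

# ---------------------------------------------------------------------------
# CircularSummary
# ---------------------------------------------------------------------------

#' Circular mean direction with confidence interval
#'
#' @slot meanAngle mean direction in degrees [0, 360).
#' @slot ciHalfwidth halfwidth of the confidence interval (degrees).
#' @slot resultantLength mean resultant length in [0, 1].
#' @slot n sample size.
#' @slot confidence confidence level used.
#' @slot method "fisher" (dispersion-based) or "bootstrap".
#' @export
setClass("CircularSummary",
  representation(meanAngle = "numeric", ciHalfwidth = "numeric",
                 resultantLength = "numeric", n = "integer",
                 confidence = "numeric", method = "character")
)

setValidity("CircularSummary", function(object) {
  if (object@resultantLength < 0 || object@resultantLength > 1 + 1e-12)
    return("resultantLength must lie in [0, 1]")
  if (object@ciHalfwidth < 0) return("ciHalfwidth must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# GeneralizationProfile
# ---------------------------------------------------------------------------

#' Distribution of signed prediction offsets of a direction classifier
#'
#' For each signed offset (predicted minus true label, wrapped to
#' (-180, 180]) on the eight-direction lattice, the fraction of test
#' predictions landing in that bin.
#'
#' @slot offsets the offset bins, degrees.
#' @slot fraction fraction of predictions per bin (sums to 1).
#' @slot trainPosture,testPosture posture of the training and test data.
#' @slot nTest number of test predictions.
#' @export
setClass("GeneralizationProfile",
  representation(offsets = "numeric", fraction = "numeric",
                 trainPosture = "character", testPosture = "character",
                 nTest = "integer")
)

setValidity("GeneralizationProfile", function(object) {
  if (length(object@offsets) != length(object@fraction))
    return("offsets and fraction must have equal length")
  if (any(object@fraction < -1e-12))
    return("fractions must be nonnegative")
  if (object@nTest > 0 && abs(sum(object@fraction) - 1) > 1e-9)
    return("fractions must sum to 1")
  TRUE
})

# ---------------------------------------------------------------------------
# AsymmetryResult
# ---------------------------------------------------------------------------

#' Paired contrast of asymmetry indices between conditions
#'
#' Summary of per-participant asymmetry indices under two conditions
#' (typically within-posture vs across-posture generalization) with a paired
#' t-test, Bonferroni-corrected over a stated number of comparisons.
#'
#' @slot withinByParticipant,acrossByParticipant per-participant indices.
#' @slot indexWithin,indexAcross condition means.
#' @slot difference mean(across - within).
#' @slot statistic paired t statistic (NA when degenerate).
#' @slot df degrees of freedom.
#' @slot pValueRaw uncorrected p-value.
#' @slot pValue Bonferroni-corrected p-value (capped at 1).
#' @slot nComparisons correction factor used.
#' @slot degenerate TRUE when the paired differences had zero variance.
#' @export
setClass("AsymmetryResult",
  representation(withinByParticipant = "numeric",
                 acrossByParticipant = "numeric",
                 indexWithin = "numeric", indexAcross = "numeric",
                 difference = "numeric", statistic = "numeric",
                 df = "numeric", pValueRaw = "numeric", pValue = "numeric",
                 nComparisons = "integer", degenerate = "logical")
)

# ---------------------------------------------------------------------------
# CommonDecoder
# ---------------------------------------------------------------------------

#' A linear common decoder from voxel patterns to 2-D aiming vectors
#'
#' A single weight matrix shared by both postures that maps a multi-voxel
#' pattern to the 2-D vectorial representation of the aiming direction; the
#' Mid-posture targets are rotated by the candidate coordinate rotation before
#' fitting, so the decoder is "common" to the two frames up to that rotation.
#'
#' @slot w 2 x N weight matrix (N = number of features).
#' @slot intercept length-2 intercept.
#' @slot deltaTheta rotation angle (degrees) the decoder was fitted under.
#' @slot lambda regularization strength used.
#' @slot penalty "ridge" or "lasso".
#' @export
setClass("CommonDecoder",
  representation(w = "matrix", intercept = "numeric", deltaTheta = "numeric",
                 lambda = "numeric", penalty = "character")
)

setValidity("CommonDecoder", function(object) {
  if (nrow(object@w) != 2L) return("w must have 2 rows")
  if (length(object@intercept) != 2L) return("intercept must have length 2")
  TRUE
})

# ---------------------------------------------------------------------------
# CoordinateIndexEstimate
# ---------------------------------------------------------------------------

#' Prediction-error curve over candidate rotation angles and its minimizer
#'
#' The cross-validated mean squared error of the common decoder's predicted
#' aiming vector at each candidate rotation angle, together with the angle at
#' the minimum (the coordinate index of the region). A curve that is flat to
#' numerical precision is flagged uninformative and the index is \code{NA}.
#'
#' @slot grid candidate rotation angles (degrees).
#' @slot errorCurve mean squared prediction error per grid angle.
#' @slot foldErrors outer-fold x grid matrix of test errors.
#' @slot deltaThetaHat the estimated coordinate index (degrees) or NA.
#' @slot uninformative TRUE when the curve is flat within tolerance.
#' @slot lambdaByFold regularization chosen on inner folds, per outer fold.
#' @slot penalty estimator family used.
#' @slot deltaThetaHatNested index chosen on inner folds (NA unless the
#'   fully-nested mode was requested).
#' @slot participantId participant identifier (NA if unset).
#' @export
setClass("CoordinateIndexEstimate",
  representation(grid = "numeric", errorCurve = "numeric",
                 foldErrors = "matrix", deltaThetaHat = "numeric",
                 uninformative = "logical", lambdaByFold = "numeric",
                 penalty = "character", deltaThetaHatNested = "numeric",
                 participantId = "integer")
)

setValidity("CoordinateIndexEstimate", function(object) {
  if (length(object@errorCurve) != length(object@grid))
    return("errorCurve must match the grid length")
  if (any(object@errorCurve < -1e-12))
    return("errorCurve values must be >= 0")
  if (!object@uninformative && !is.na(object@deltaThetaHat) &&
      !any(abs(object@grid - object@deltaThetaHat) < 1e-9))
    return("deltaThetaHat must be a grid point")
  TRUE
})

# ---------------------------------------------------------------------------
# DirectionClassifier
# ---------------------------------------------------------------------------

#' One-vs-rest linear-margin classifier over the eight aiming directions
#'
#' Eight binary linear support-vector machines, one per direction label;
#' prediction takes the label with the largest decision value, with ties
#' broken toward the smallest label angle.
#'
#' @slot models list of binary SVM fits, in ascending label order.
#' @slot labels the direction labels (degrees), ascending.
#' @slot cost SVM regularization constant.
#' @export
setClass("DirectionClassifier",
  representation(models = "list", labels = "numeric", cost = "numeric")
)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n",
      sprintf("  %d participant(s), %d voxels x %d units/voxel\n",
              object@nParticipants, object@nVoxels, object@nNeuronsPerVoxel),
      sprintf("  deltaThetaTrue = %g deg (jitter sd %g), noise sd %g\n",
              object@deltaThetaTrue, object@pdRotationJitterSd, object@noiseSd),
      sprintf("  design: %d runs/posture x %d trials/run, %d directions, seed %d\n",
              object@runsPerPosture, object@trialsPerRun, object@nDirections,
              object@seed), sep = "")
})

setMethod("show", "CosineFit", function(object) {
  if (object@untuned) {
    cat(sprintf("CosineFit (untuned): b = %.4g, n = %d\n", object@b, object@n))
  } else {
    cat(sprintf("CosineFit: k = %.4g, mu = %.2f deg, b = %.4g (rss %.4g, n %d)\n",
                object@k, object@mu, object@b, object@rss, object@n))
  }
})

setMethod("show", "CircularSummary", function(object) {
  cat(sprintf("CircularSummary: mean %.2f deg +/- %.2f (%.0f%% CI, %s), R = %.3f, n = %d\n",
              object@meanAngle, object@ciHalfwidth, 100 * object@confidence,
              object@method, object@resultantLength, object@n))
})

setMethod("show", "GeneralizationProfile", function(object) {
  cat(sprintf("GeneralizationProfile (train %s, test %s, n = %d)\n",
              object@trainPosture, object@testPosture, object@nTest))
  print(stats::setNames(round(object@fraction, 4), paste0(object@offsets, "deg")))
})

setMethod("show", "CommonDecoder", function(object) {
  cat(sprintf("CommonDecoder: 2 x %d weights, deltaTheta = %g deg, %s penalty (lambda %.4g)\n",
              ncol(object@w), object@deltaTheta, object@penalty, object@lambda))
})

setMethod("show", "CoordinateIndexEstimate", function(object) {
  if (object@uninformative) {
    cat("CoordinateIndexEstimate: uninformative (flat error curve)\n")
  } else {
    cat(sprintf("CoordinateIndexEstimate: deltaThetaHat = %g deg (grid %g..%g, %d points)\n",
                object@deltaThetaHat, min(object@grid), max(object@grid),
                length(object@grid)))
  }
})

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf("AsymmetryResult: within %.4f, across %.4f, diff %.4f; corrected p = %.3g (x%d)\n",
              object@indexWithin, object@indexAcross, object@difference,
              object@pValue, object@nComparisons))
})
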