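#' Compensate the hemodynamic delay of a run series
#'
#' Shifts the signal earlier in time by \code{delaySeconds} (which must be a
#' whole number of volumes), so that volumes line up with the task events
#' that caused them. The leading volumes that scroll out of the run are
#' dropped; block onsets are unchanged.
#'
#' @param series a \linkS4class{RunSeries}.
#' @param delaySeconds hemodynamic delay, default 4 s.
#' @return The shifted \linkS4class{RunSeries}.
#' @export
shiftHemodynamic <- function(series, delaySeconds = 4) {
  stopifnot(is(series, "RunSeries"))
  if (delaySeconds %% series@trSeconds != 0)
    .stopf("configuration error: delay (%g s) must be a multiple of the TR (%g s)",
           delaySeconds, series@trSeconds)
  k <- as.integer(delaySeconds / series@trSeconds)
  if (k == 0L) return(series)
  nT <- nrow(series@volumes)
  if (k >= nT) .stopf("delay exceeds the series length")
  series@volumes <- series@volumes[(k + 1L):nT, , drop = FALSE]
  validObject(series)
  series
}

# Volume indices of the initial rest period.
.restIndices <- function(series) {
  seq_len(as.integer(series@restOnsetSeconds / series@trSeconds))
}

# Volume indices after the last task block (terminal rest), if any.
.tailIndices <- function(series) {
  lastEnd <- max(series@blockOnsets) + series@blockDurationSeconds
  first <- as.integer(lastEnd / series@trSeconds) + 1L
  nT <- nrow(series@volumes)
  if (first > nT) integer(0) else first:nT
}

#' Normalize each voxel by its initial-rest mean
#'
#' Divides every voxel's time course by its mean over the initial rest
#' period, so rest sits at 1 and task responses are expressed as fractional
#' signal change. A voxel whose rest mean is numerically degenerate (below
#' 1e-12 of the run's mean absolute signal) raises an error naming the voxel.
#'
#' @param series a \linkS4class{RunSeries}.
#' @return The normalized \linkS4class{RunSeries}.
#' @export
normalizeBaseline <- function(series) {
  stopifnot(is(series, "RunSeries"))
  rest <- .restIndices(series)
  if (length(rest) < 1L) .stopf("no rest period present")
  m <- colMeans(series@volumes[rest, , drop = FALSE])
  floorVal <- 1e-12 * mean(abs(series@volumes))
  bad <- which(abs(m) <= floorVal)
  if (length(bad))
    .stopf("degenerate baseline in voxel %d: rest mean %.3g below floor",
           bad[1], m[bad[1]])
  series@volumes <- sweep(series@volumes, 2, m, "/")
  series
}

#' Remove a linear trend from each voxel
#'
#' Fits a least-squares line per voxel and removes its slope while re-adding
#' the run mean, so the signal scale is preserved. By default
#' (\code{method = "rest"}) the line is fitted on the rest volumes only
#' (initial and terminal rest), so task-evoked responses cannot bias the
#' trend estimate and a noiseless rendered run round-trips exactly;
#' \code{method = "all"} fits on every volume.
#'
#' @param series a \linkS4class{RunSeries} with at least 3 volumes.
#' @param method "rest" (default) or "all"; which volumes inform the fit.
#' @return The detrended \linkS4class{RunSeries}.
#' @export
detrendLinear <- function(series, method = c("rest", "all")) {
  stopifnot(is(series, "RunSeries"))
  method <- match.arg(method)
  nT <- nrow(series@volumes)
  if (nT < 3L) .stopf("size error: need at least 3 volumes, got %d", nT)
  idx <- if (method == "rest") c(.restIndices(series), .tailIndices(series))
         else seq_len(nT)
  if (length(idx) < 2L) idx <- seq_len(nT)
  t_fit <- idx - mean(idx)
  slope <- crossprod(t_fit, series@volumes[idx, , drop = FALSE]) / sum(t_fit^2)
  t_all <- seq_len(nT) - mean(seq_len(nT))
  series@volumes <- series@volumes - outer(t_all, drop(slope))
  series
}

#' Extract trial patterns from a conditioned run series
#'
#' Emits samples from the task volumes of each block, labeled with the
#' block's aiming direction: either one sample per volume (default; a 6-s
#' block at TR 2 yields 3 samples per trial) or one averaged sample per
#' trial. The series is expected to have been shifted, normalized and
#' detrended first.
#'
#' @param series a \linkS4class{RunSeries} or a list of them.
#' @param mode "volume" or "trial".
#' @return A \linkS4class{TrialPatterns}.
#' @export
extractTrialPatterns <- function(series, mode = c("volume", "trial")) {
  mode <- match.arg(mode)
  if (is(series, "RunSeries")) series <- list(series)
  parts <- lapply(series, function(s) {
    vpb <- as.integer(s@blockDurationSeconds / s@trSeconds)
    nT <- nrow(s@volumes)
    first <- as.integer(s@blockOnsets / s@trSeconds) + 1L
    if (any(first + vpb - 1L > nT))
      .stopf("boundary error: block extends past the end of the series")
    rows <- lapply(first, function(f) f:(f + vpb - 1L))
    if (mode == "volume") {
      resp <- s@volumes[unlist(rows), , drop = FALSE]
      dir <- rep(s@direction, each = vpb)
    } else {
      resp <- do.call(rbind, lapply(rows, function(rr)
        colMeans(s@volumes[rr, , drop = FALSE])))
      dir <- s@direction
    }
    list(resp = resp, dir = dir, post = s@posture, run = s@runId,
         part = s@participantId)
  })
  TrialPatterns(do.call(rbind, lapply(parts, `[[`, "resp")),
                direction = unlist(lapply(parts, `[[`, "dir")),
                posture = unlist(lapply(parts, function(p)
                  rep(p$post, length(p$dir)))),
                run = unlist(lapply(parts, function(p)
                  rep(p$run, length(p$dir)))),
                participant = unlist(lapply(parts, function(p)
                  rep(p$part, length(p$dir)))))
}

#' Standardize each sample across its features
#'
#' Z-transforms every sample (row) of the pattern matrix to mean 0 and
#' standard deviation 1 across features, which removes global activation
#' differences between the postural conditions. Zero-variance samples are
#' replaced by zeros, recorded in \code{metadata(x)$zeroVarianceSamples}, and
#' reported with a warning.
#'
#' @param x a \linkS4class{TrialPatterns} with at least 2 features.
#' @return The standardized \linkS4class{TrialPatterns}.
#' @export
zscorePatterns <- function(x) {
  stopifnot(is(x, "TrialPatterns"))
  M <- assay(x, "responses")           # features x samples
  if (nrow(M) < 2L) .stopf("size error: need at least 2 features to z-score")
  n <- nrow(M)
  mu <- colMeans(M)
  sdv <- sqrt(pmax(colSums(M^2) - n * mu^2, 0) / (n - 1))
  zero <- which(sdv == 0)
  sdv[zero] <- 1
  M <- sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
  if (length(zero)) {
    M[, zero] <- 0
    warning(sprintf("%d zero-variance sample(s) replaced by zeros", length(zero)))
  }
  assay(x, "responses") <- M
  metadata(x)$zeroVarianceSamples <- zero
  x
}

#' Full signal-conditioning pipeline for a set of runs
#'
#' Applies the fixed stage order: hemodynamic shift, baseline normalization,
#' rest-based linear detrending, trial-pattern extraction, and per-sample
#' z-scoring.
#'
#' @param runs a list of \linkS4class{RunSeries}.
#' @param delaySeconds hemodynamic delay.
#' @param mode sample extraction mode ("volume" or "trial").
#' @param detrendMethod trend-fit volumes ("rest" or "all").
#' @param zscore standardize samples after extraction (default TRUE).
#' @return A \linkS4class{TrialPatterns}.
#' @export
preprocessRuns <- function(runs, delaySeconds = 4, mode = "volume",
                           detrendMethod = "rest", zscore = TRUE) {
  if (is(runs, "RunSeries")) runs <- list(runs)
  cond <- lapply(runs, function(s)
    detrendLinear(normalizeBaseline(shiftHemodynamic(s, delaySeconds)),
                  method = detrendMethod))
  x <- extractTrialPatterns(cond, mode = mode)
  if (zscore) x <- zscorePatterns(x) else x
}
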