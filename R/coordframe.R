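#' 2-D rotation matrix
#'
#' The standard counterclockwise rotation
#' \deqn{R(\Delta\theta) = \begin{pmatrix} \cos\Delta\theta & -\sin\Delta\theta \\
#'   \sin\Delta\theta & \cos\Delta\theta \end{pmatrix}}
#' used to rotate the predicted aiming vector of the Mid posture into the
#' extrinsic frame.
#'
#' @param deltaTheta angle in degrees.
#' @return A 2 x 2 orthogonal matrix with determinant +1.
#' @examples
#' rotationMatrix(90) %*% c(1, 0)  # (0, 1)
#' @export
rotationMatrix <- function(deltaTheta) {
  if (!is.finite(deltaTheta)) .stopf("rotation angle must be finite")
  c <- .cosd(deltaTheta); s <- .sind(deltaTheta)
  matrix(c(c, s, -s, c), nrow = 2)
}

#' Encode direction labels as unit aiming vectors
#'
#' Maps each label (degrees in the task frame, where the Pro-posture
#' extension direction is 0) to the unit vector (cos, sin).
#'
#' @param label numeric vector of directions in degrees.
#' @return An n x 2 matrix of unit vectors.
#' @examples
#' encodeDirection(c(0, 90, 225))
#' @export
encodeDirection <- function(label) {
  cbind(cos = .cosd(label), sin = .sind(label))
}

# ---------------------------------------------------------------------------
# Ridge machinery
#
# The stacked regression pairs Pro samples with targets v(theta) and Mid
# samples with targets R(-dtheta) v(theta); in row form the Mid target block
# is U_mid %*% R(dtheta). Because the design matrix is fixed over the
# rotation grid and the ridge solution is linear in the targets, one
# eigendecomposition of the centered Gram matrix per cross-validation fold
# evaluates every grid angle and every regularization strength by small
# matrix products.
# ---------------------------------------------------------------------------

# Per-run sufficient statistics: Gram matrices, feature/target sums.
.runStats <- function(X, U, runIdx) {
  lapply(runIdx, function(idx) {
    Xr <- X[idx, , drop = FALSE]
    list(G = crossprod(Xr), s = colSums(Xr), Txu = crossprod(Xr, U[idx, , drop = FALSE]),
         usum = colSums(U[idx, , drop = FALSE]), n = length(idx), idx = idx)
  })
}

# Fit + evaluate the ridge common decoder on one fold, for every grid angle
# and every lambda at once. The target cross-covariance is assembled once
# (it does not depend on lambda); each lambda is then a rescaling in the
# eigenbasis of the centered training Gram matrix.
# Returns a length(lambdas) x nGrid matrix of mean squared test errors.
.ridgeFoldErrors <- function(tr, X, U, testPro, testMid, Rall, lambdas) {
  eig <- tr$eig; agg <- tr$agg; xbar <- tr$xbar
  nG <- ncol(Rall) / 2L
  nTr <- agg$n
  # Target column sums per grid angle (length 2nG, blocks of 2)
  ybarAll <- (rep(agg$uPro, nG) +
                as.numeric(matrix(agg$uMid, nrow = 1) %*% Rall)) / nTr
  # Centered cross-covariance X'Y per grid angle
  Ball <- matrix(rep(agg$APro, nG), nrow = nrow(agg$APro)) + agg$AMid %*% Rall
  Ball <- Ball - outer(xbar, nTr * ybarAll)
  Pm <- crossprod(eig$vectors, Ball)                      # p x 2nG
  vals <- pmax(eig$values, 0)
  XproV <- t(t(X[testPro, , drop = FALSE]) - xbar) %*% eig$vectors
  XmidV <- t(t(X[testMid, , drop = FALSE]) - xbar) %*% eig$vectors
  Upro <- U[testPro, , drop = FALSE]
  UmidR <- U[testMid, , drop = FALSE] %*% Rall            # nmid x 2nG
  nTe <- length(testPro) + length(testMid)
  errs <- matrix(0, nrow = length(lambdas), ncol = nG)
  for (li in seq_along(lambdas)) {
    Wt <- Pm / (vals + lambdas[li])
    Zp <- XproV %*% Wt
    Zm <- XmidV %*% Wt
    for (g in seq_len(nG)) {
      c1 <- 2L * g - 1L
      # Rotating the Mid prediction by R(dtheta) and comparing to v is
      # norm-identical to comparing the raw prediction to U %*% R(dtheta).
      e <- sum((Zp[, c1] + ybarAll[c1] - Upro[, 1])^2) +
           sum((Zp[, c1 + 1L] + ybarAll[c1 + 1L] - Upro[, 2])^2) +
           sum((Zm[, c1] + ybarAll[c1] - UmidR[, c1])^2) +
           sum((Zm[, c1 + 1L] + ybarAll[c1 + 1L] - UmidR[, c1 + 1L])^2)
      errs[li, g] <- e / nTe
    }
  }
  errs
}

# Aggregate training-side statistics over a set of run stats.
.aggStats <- function(statsPro, statsMid) {
  allS <- c(statsPro, statsMid)
  G <- Reduce(`+`, lapply(allS, `[[`, "G"))
  s <- Reduce(`+`, lapply(allS, `[[`, "s"))
  n <- sum(vapply(allS, `[[`, numeric(1), "n"))
  list(G = G, s = s, n = n,
       APro = Reduce(`+`, lapply(statsPro, `[[`, "Txu")),
       AMid = Reduce(`+`, lapply(statsMid, `[[`, "Txu")),
       uPro = Reduce(`+`, lapply(statsPro, `[[`, "usum")),
       uMid = Reduce(`+`, lapply(statsMid, `[[`, "usum")))
}

# Training aggregate for a fold as "totals minus held-out run pairs";
# run-pair indices beyond the paired folds always stay in training.
.dropStats <- function(tot, statsPro, statsMid, excl) {
  for (i in excl) {
    tot$G <- tot$G - statsPro[[i]]$G - statsMid[[i]]$G
    tot$s <- tot$s - statsPro[[i]]$s - statsMid[[i]]$s
    tot$n <- tot$n - statsPro[[i]]$n - statsMid[[i]]$n
    tot$APro <- tot$APro - statsPro[[i]]$Txu
    tot$AMid <- tot$AMid - statsMid[[i]]$Txu
    tot$uPro <- tot$uPro - statsPro[[i]]$usum
    tot$uMid <- tot$uMid - statsMid[[i]]$usum
  }
  tot
}

# Centered-Gram eigendecomposition for a training aggregate (cached).
.trainEig <- function(agg) {
  xbar <- agg$s / agg$n
  Gc <- agg$G - agg$n * tcrossprod(xbar)
  list(eig = eigen(Gc, symmetric = TRUE), xbar = xbar)
}

#' Fit the common decoder at a fixed rotation angle
#'
#' Fits the single linear map from multi-voxel patterns to 2-D aiming
#' vectors on the stacked two-posture design: Pro samples are paired with
#' the target vector of their label and Mid samples with that vector rotated
#' by the inverse of the candidate rotation. A fitted 2-vector intercept is
#' included. The ridge penalty has a closed-form solution; the lasso penalty
#' (grouped across the two output dimensions) is fitted with
#' \pkg{glmnet}. When \code{lambda} is NULL it is selected by
#' leave-one-run-out cross-validation over the run pairs.
#'
#' @param x a \linkS4class{TrialPatterns} containing both postures.
#' @param deltaTheta candidate rotation angle, degrees.
#' @param penalty "ridge" or "lasso".
#' @param lambda regularization strength, or NULL to select by run-wise CV.
#' @param lambdas candidate grid used when \code{lambda} is NULL.
#' @return A \linkS4class{CommonDecoder}.
#' @export
fitCommonDecoder <- function(x, deltaTheta, penalty = c("ridge", "lasso"),
                             lambda = NULL,
                             lambdas = 10^seq(-2, 3, length.out = 6)) {
  stopifnot(is(x, "TrialPatterns"))
  penalty <- match.arg(penalty)
  if (length(unique(posture(x))) < 2L)
    .stopf("design error: both postures are required to fit the common decoder")
  X <- .featMatrix(x)
  U <- encodeDirection(aimDirection(x))
  isMid <- posture(x) == "Mid"
  Y <- U
  Y[isMid, ] <- U[isMid, , drop = FALSE] %*% rotationMatrix(deltaTheta)
  if (is.null(lambda))
    lambda <- .selectLambdaSimple(x, deltaTheta, penalty, lambdas)
  if (penalty == "ridge") {
    xbar <- colMeans(X); ybar <- colMeans(Y)
    Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
    M <- crossprod(Xc)
    diag(M) <- diag(M) + lambda
    Wt <- solve(M, crossprod(Xc, Yc))       # p x 2
    intercept <- ybar - drop(crossprod(Wt, xbar))
    new("CommonDecoder", w = t(Wt), intercept = intercept,
        deltaTheta = deltaTheta, lambda = lambda, penalty = "ridge")
  } else {
    fit <- glmnet::glmnet(X, Y, family = "mgaussian", alpha = 1,
                          lambda = lambda, standardize = FALSE,
                          intercept = TRUE)
    W <- rbind(as.numeric(fit$beta[[1]]), as.numeric(fit$beta[[2]]))
    new("CommonDecoder", w = W, intercept = as.numeric(fit$a0),
        deltaTheta = deltaTheta, lambda = lambda, penalty = "lasso")
  }
}

# Leave-one-run-pair-out selection of lambda at a fixed angle (used by the
# standalone fitter; errorCurve() has its own nested selection).
.selectLambdaSimple <- function(x, deltaTheta, penalty, lambdas) {
  pr <- sort(unique(runId(x)[posture(x) == "Pro"]))
  mr <- sort(unique(runId(x)[posture(x) == "Mid"]))
  nF <- min(length(pr), length(mr))
  if (nF < 2L) return(lambdas[ceiling(length(lambdas) / 2)])
  errs <- vapply(lambdas, function(lam) {
    e <- 0
    for (f in seq_len(nF)) {
      te <- runId(x) %in% c(pr[f], mr[f])
      dec <- fitCommonDecoder(x[, !te], deltaTheta, penalty = penalty,
                              lambda = lam)
      e <- e + aimPredictionError(dec, x[, te])
    }
    e / nF
  }, numeric(1))
  lambdas[which.min(errs)]
}

#' Predict aiming vectors with a common decoder
#'
#' @param decoder a \linkS4class{CommonDecoder}.
#' @param newdata a samples x features matrix or \linkS4class{TrialPatterns}.
#' @return An n x 2 matrix of predicted aiming vectors (extrinsic frame for
#'   Pro samples; multiply Mid predictions by
#'   \code{rotationMatrix(deltaTheta)} to express them extrinsically).
#' @export
predictAim <- function(decoder, newdata) {
  stopifnot(is(decoder, "CommonDecoder"))
  X <- if (is(newdata, "TrialPatterns")) .featMatrix(newdata)
       else as.matrix(newdata)
  sweep(X %*% t(decoder@w), 2, decoder@intercept, "+")
}

#' Mean squared aiming-vector prediction error
#'
#' Squared Euclidean distance between each predicted 2-vector and the unit
#' target vector of the sample's label, averaged over samples; Mid-posture
#' predictions are rotated into the extrinsic frame by the decoder's fitted
#' rotation before comparison.
#'
#' @param decoder a \linkS4class{CommonDecoder}.
#' @param x a \linkS4class{TrialPatterns}.
#' @return The mean squared error (a single number).
#' @export
aimPredictionError <- function(decoder, x) {
  stopifnot(is(x, "TrialPatterns"))
  pred <- predictAim(decoder, x)
  U <- encodeDirection(aimDirection(x))
  isMid <- posture(x) == "Mid"
  if (any(isMid)) {
    R <- rotationMatrix(decoder@deltaTheta)
    pred[isMid, ] <- pred[isMid, , drop = FALSE] %*% t(R)
  }
  mean(rowSums((pred - U)^2))
}

#' Cross-validated error curve over candidate rotation angles
#'
#' The core computation: for every angle on the grid, the common decoder is
#' fitted on the training portion of each outer fold and the mean squared
#' error of the predicted aiming vectors is accumulated over the outer test
#' folds. The outer loop leaves one run of each posture out; the inner loop
#' (leave-one-run-pair-out over the remaining runs) selects the
#' regularization strength per outer fold, evaluated on a coarse 45-degree
#' angle lattice and averaged. The curve is the mean over outer folds, and
#' its minimizer is the coordinate index of the data.
#'
#' @param x a \linkS4class{TrialPatterns} for one participant with at least
#'   3 runs per posture (for the nested selection).
#' @param grid candidate rotation angles, degrees; default -45 to 315 in
#'   5-degree steps.
#' @param penalty "ridge" (closed form; default) or "lasso" (glmnet).
#' @param lambdas candidate regularization strengths for the inner folds.
#' @param wFit "outer" (default): refit the decoder within every outer fold;
#'   "full": fit once on all runs per angle and report in-sample error.
#' @param fullyNested also select the rotation angle on inner folds within
#'   each outer fold and report the circular mean of the per-fold choices in
#'   \code{deltaThetaHatNested} (bias check).
#' @return A \linkS4class{CoordinateIndexEstimate}.
#' @export
errorCurve <- function(x, grid = seq(-45, 315, by = 5),
                       penalty = c("ridge", "lasso"),
                       lambdas = 10^seq(-2, 3, length.out = 6),
                       wFit = c("outer", "full"), fullyNested = FALSE) {
  stopifnot(is(x, "TrialPatterns"))
  penalty <- match.arg(penalty)
  wFit <- match.arg(wFit)
  part <- unique(participantId(x))
  if (length(part) != 1L)
    .stopf("errorCurve expects a single participant's data")
  pr <- sort(unique(runId(x)[posture(x) == "Pro"]))
  mr <- sort(unique(runId(x)[posture(x) == "Mid"]))
  if (length(pr) == 0L || length(mr) == 0L)
    .stopf("design error: both postures are required")
  nF <- min(length(pr), length(mr))
  if (wFit == "outer" && nF < 3L)
    .stopf("CV error: need at least 3 runs per posture for nested cross-validation")
  if (penalty == "lasso")
    return(.errorCurveLasso(x, grid, lambdas, wFit, part))

  X <- .featMatrix(x)
  U <- encodeDirection(aimDirection(x))
  rid <- runId(x)
  statsPro <- .runStats(X, U, lapply(pr, function(r)
    which(rid == r & posture(x) == "Pro")))
  statsMid <- .runStats(X, U, lapply(mr, function(r)
    which(rid == r & posture(x) == "Mid")))
  Rall <- do.call(cbind, lapply(grid, rotationMatrix))
  coarse <- seq(0, 315, by = 45)
  RallCoarse <- do.call(cbind, lapply(coarse, rotationMatrix))

  if (wFit == "full") {
    agg <- .aggStats(statsPro, statsMid)
    tr <- c(.trainEig(agg), list(agg = agg))
    lam <- lambdas[1]
    errs <- .ridgeFoldErrors(tr, X, U,
                             unlist(lapply(statsPro, `[[`, "idx")),
                             unlist(lapply(statsMid, `[[`, "idx")),
                             Rall, lam)
    return(.finalizeEstimate(grid, errs, lam, "ridge", NA_real_, part))
  }

  totals <- .aggStats(statsPro, statsMid)
  eigCache <- new.env(parent = emptyenv())
  getEig <- function(excl) {
    key <- paste(sort(excl), collapse = "_")
    if (!is.null(eigCache[[key]])) return(eigCache[[key]])
    agg <- .dropStats(totals, statsPro, statsMid, excl)
    val <- c(.trainEig(agg), list(agg = agg))
    eigCache[[key]] <- val
    val
  }

  foldErrors <- matrix(NA_real_, nrow = nF, ncol = length(grid))
  lambdaByFold <- numeric(nF)
  nestedPick <- rep(NA_real_, nF)
  for (f in seq_len(nF)) {
    inner <- setdiff(seq_len(nF), f)
    innerErr <- matrix(0, nrow = length(lambdas), ncol = length(coarse))
    fullInner <- if (fullyNested)
      matrix(0, nrow = length(lambdas), ncol = length(grid)) else NULL
    for (g in inner) {
      tr <- getEig(c(f, g))
      tPro <- statsPro[[g]]$idx; tMid <- statsMid[[g]]$idx
      innerErr <- innerErr +
        .ridgeFoldErrors(tr, X, U, tPro, tMid, RallCoarse, lambdas)
      if (fullyNested)
        fullInner <- fullInner +
          .ridgeFoldErrors(tr, X, U, tPro, tMid, Rall, lambdas)
    }
    li <- which.min(rowMeans(innerErr))
    lambdaByFold[f] <- lambdas[li]
    if (fullyNested)
      nestedPick[f] <- grid[.argminTieBreak(grid, fullInner[li, ])]
    tr <- getEig(f)
    foldErrors[f, ] <- .ridgeFoldErrors(tr, X, U, statsPro[[f]]$idx,
                                        statsMid[[f]]$idx, Rall,
                                        lambdaByFold[f])
  }
  nested <- if (fullyNested) .circMean(nestedPick)$mean else NA_real_
  .finalizeEstimate(grid, foldErrors, lambdaByFold, "ridge", nested, part)
}

# Straightforward (slow) lasso path over the grid; intended for small data.
.errorCurveLasso <- function(x, grid, lambdas, wFit, part) {
  pr <- sort(unique(runId(x)[posture(x) == "Pro"]))
  mr <- sort(unique(runId(x)[posture(x) == "Mid"]))
  nF <- min(length(pr), length(mr))
  coarse <- seq(0, 315, by = 45)
  if (wFit == "full") {
    errs <- vapply(grid, function(dt) {
      dec <- fitCommonDecoder(x, dt, penalty = "lasso", lambda = lambdas[1])
      aimPredictionError(dec, x)
    }, numeric(1))
    return(.finalizeEstimate(grid, matrix(errs, nrow = 1), lambdas[1],
                             "lasso", NA_real_, part))
  }
  foldErrors <- matrix(NA_real_, nrow = nF, ncol = length(grid))
  lambdaByFold <- numeric(nF)
  for (f in seq_len(nF)) {
    teRuns <- c(pr[f], mr[f])
    isTe <- runId(x) %in% teRuns
    xtr <- x[, !isTe]; xte <- x[, isTe]
    innerErr <- matrix(0, nrow = length(lambdas), ncol = length(coarse))
    for (g in setdiff(seq_len(nF), f)) {
      giRuns <- c(pr[g], mr[g])
      isGi <- runId(xtr) %in% giRuns
      xin <- xtr[, !isGi]; xiv <- xtr[, isGi]
      for (ci in seq_along(coarse)) for (li in seq_along(lambdas)) {
        dec <- fitCommonDecoder(xin, coarse[ci], penalty = "lasso",
                                lambda = lambdas[li])
        innerErr[li, ci] <- innerErr[li, ci] + aimPredictionError(dec, xiv)
      }
    }
    lambdaByFold[f] <- lambdas[which.min(rowMeans(innerErr))]
    foldErrors[f, ] <- vapply(grid, function(dt) {
      dec <- fitCommonDecoder(xtr, dt, penalty = "lasso",
                              lambda = lambdaByFold[f])
      aimPredictionError(dec, xte)
    }, numeric(1))
  }
  .finalizeEstimate(grid, foldErrors, lambdaByFold, "lasso", NA_real_, part)
}

# Tie-break: among exact minima prefer the smallest |angle|; equal
# magnitudes resolve to the positive angle.
.argminTieBreak <- function(grid, errs) {
  cand <- which(errs == min(errs))
  cand[order(abs(grid[cand]), grid[cand] < 0)][1]
}

.finalizeEstimate <- function(grid, foldErrors, lambdaByFold, penalty,
                              nested, part) {
  curve <- colMeans(foldErrors)
  scale <- max(1, abs(mean(curve)))
  flat <- (max(curve) - min(curve)) <= 1e-12 * scale
  dth <- if (flat) NA_real_ else grid[.argminTieBreak(grid, curve)]
  new("CoordinateIndexEstimate", grid = grid, errorCurve = curve,
      foldErrors = foldErrors, deltaThetaHat = dth, uninformative = flat,
      lambdaByFold = lambdaByFold, penalty = penalty,
      deltaThetaHatNested = nested,
      participantId = as.integer(part))
}

#' Construct a CoordinateIndexEstimate from a precomputed curve
#'
#' @param grid candidate angles, degrees.
#' @param errors mean squared error per grid angle.
#' @param participant participant id.
#' @return A \linkS4class{CoordinateIndexEstimate}.
#' @export
coordinateIndexEstimate <- function(grid, errors, participant = NA_integer_) {
  .finalizeEstimate(grid, matrix(errors, nrow = 1), NA_real_, "precomputed",
                    NA_real_, participant)
}

#' Read off the coordinate index from an error curve
#'
#' Returns the grid angle minimizing the cross-validated prediction error.
#' Exact ties break toward the smallest absolute angle (closest to the
#' extrinsic frame), with equal magnitudes resolving to the positive angle.
#' A curve that is flat to within 1e-12 (relative) is uninformative and
#' yields \code{NA} with a warning; this mirrors regions whose error
#' functions carry no rotation information.
#'
#' @param estimate a \linkS4class{CoordinateIndexEstimate}.
#' @return The coordinate index in degrees, or NA if uninformative.
#' @export
estimateCoordinateIndex <- function(estimate) {
  stopifnot(is(estimate, "CoordinateIndexEstimate"))
  curve <- estimate@errorCurve
  scale <- max(1, abs(mean(curve)))
  if ((max(curve) - min(curve)) <= 1e-12 * scale) {
    warning("uninformative: error curve is flat within tolerance")
    return(NA_real_)
  }
  estimate@grid[.argminTieBreak(estimate@grid, curve)]
}

#' Group-level circular statistics of per-participant coordinate indices
#'
#' Circular mean and confidence interval of the coordinate indices across
#' participants, plus one-sample circular tests against each reference frame
#' (0 degrees extrinsic and 90 degrees joint-like by default; the empirical
#' muscle angle may be added).
#'
#' @param indices per-participant coordinate indices, degrees (n >= 3).
#' @param references reference angles to test against.
#' @param confidence confidence level.
#' @param bootstrap,bootSeed bootstrap settings for the circular tests.
#' @return A list with \code{summary} (a \linkS4class{CircularSummary}) and
#'   \code{tests} (a data.frame with one row per reference).
#' @export
groupCoordinateIndex <- function(indices, references = c(0, 90),
                                 confidence = 0.95, bootstrap = 10000L,
                                 bootSeed = 1L) {
  indices <- indices[is.finite(indices)]
  if (length(indices) < 3L)
    .stopf("size error: need at least 3 participants, got %d", length(indices))
  summ <- circularMeanCI(indices, confidence = confidence,
                         bootstrap = bootstrap, bootSeed = bootSeed)
  tests <- do.call(rbind, lapply(references, function(ref) {
    tst <- circularOneSampleTest(indices, ref, confidence = confidence,
                                 bootstrap = bootstrap, bootSeed = bootSeed)
    data.frame(reference = ref, pValue = tst$pValue,
               ciContainsReference = tst$ciContainsReference,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
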