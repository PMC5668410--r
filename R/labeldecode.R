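#' Train a linear direction classifier
#'
#' Fits a one-vs-rest bank of binary linear support-vector machines over the
#' eight aiming-direction labels (fixed regularization constant, default
#' C = 1; no feature rescaling, since patterns are standardized upstream).
#' Prediction takes the label with the largest decision value; exact ties
#' resolve to the smallest label angle. The fit is deterministic given the
#' data.
#'
#' @param x a \linkS4class{TrialPatterns} containing at least 2 runs and all
#'   direction labels.
#' @param cost SVM regularization constant.
#' @return A \linkS4class{DirectionClassifier}.
#' @export
trainDirectionClassifier <- function(x, cost = 1) {
  stopifnot(is(x, "TrialPatterns"))
  if (length(unique(runId(x))) < 2L)
    .stopf("design error: need at least 2 runs to train")
  miss <- setdiff(seq(0, 315, by = 45), unique(aimDirection(x)))
  if (length(miss))
    .stopf("design error: label %g missing from training data", miss[1])
  .trainOvr(.featMatrix(x), aimDirection(x), cost = cost)
}

# Internal one-vs-rest trainer without the run-count precondition, used by
# cross-validation folds whose training split may hold a single run.
.trainOvr <- function(X, dir, cost = 1) {
  labels <- sort(unique(dir))
  models <- lapply(labels, function(lb) {
    y <- factor(ifelse(dir == lb, "target", "rest"),
                levels = c("target", "rest"))
    if (length(unique(y)) < 2L)
      .stopf("design error: label %g missing from training data", lb)
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  })
  new("DirectionClassifier", models = models, labels = labels, cost = cost)
}

#' Predict aiming-direction labels
#'
#' @param classifier a \linkS4class{DirectionClassifier}.
#' @param newdata a samples x features matrix or \linkS4class{TrialPatterns}.
#' @return Numeric vector of predicted labels (degrees).
#' @export
predictDirections <- function(classifier, newdata) {
  stopifnot(is(classifier, "DirectionClassifier"))
  X <- if (is(newdata, "TrialPatterns")) .featMatrix(newdata)
       else as.matrix(newdata)
  dv <- vapply(classifier@models, function(m) {
    pr <- stats::predict(m, X, decision.values = TRUE)
    d <- drop(attr(pr, "decision.values"))
    # orient so positive always means "target"
    if (grepl("^target", colnames(attr(pr, "decision.values"))[1])) d else -d
  }, numeric(nrow(X)))
  dv <- matrix(dv, nrow = nrow(X))
  # which.max returns the first maximum; columns are in ascending label
  # order, so ties break toward the smallest label angle.
  classifier@labels[apply(dv, 1, which.max)]
}

# Bin signed offsets (predicted - true) into the 45-degree lattice profile.
.profileFromOffsets <- function(offsets, trainPosture, testPosture) {
  bins <- .offsetBins()
  counts <- vapply(bins, function(b) sum(abs(.wrap180(offsets - b)) < 1e-6),
                   numeric(1))
  if (sum(counts) != length(offsets))
    .stopf("offsets do not all fall on the 45-degree lattice")
  new("GeneralizationProfile", offsets = bins,
      fraction = counts / length(offsets),
      trainPosture = trainPosture, testPosture = testPosture,
      nTest = length(offsets))
}

#' Generalization profile of the direction classifier
#'
#' When \code{trainPosture == testPosture}, evaluates by leave-one-run-out
#' cross-validation within that posture's runs; otherwise trains on all runs
#' of the training posture and tests on all runs of the other. Every test
#' prediction contributes its signed offset (predicted minus true label,
#' wrapped to (-180, 180]) to the profile. Under the package's sign
#' convention, a frame rotated clockwise by delta places the across-posture
#' mass at +delta when training on Mid and testing on Pro, and mirrored at
#' -delta for the reverse transfer.
#'
#' @param x a \linkS4class{TrialPatterns} containing the required postures.
#' @param trainPosture,testPosture "Pro" or "Mid".
#' @param cost SVM regularization constant.
#' @return A \linkS4class{GeneralizationProfile}.
#' @export
generalizationProfile <- function(x, trainPosture, testPosture, cost = 1) {
  stopifnot(is(x, "TrialPatterns"))
  trainPosture <- match.arg(trainPosture, c("Pro", "Mid"))
  testPosture <- match.arg(testPosture, c("Pro", "Mid"))
  if (trainPosture == testPosture) {
    sub <- .subsetPosture(x, trainPosture)
    runs <- sort(unique(runId(sub)))
    if (length(runs) < 2L)
      .stopf("CV error: need at least 2 runs in posture %s", trainPosture)
    offs <- unlist(lapply(runs, function(r) {
      tr <- sub[, runId(sub) != r]
      te <- sub[, runId(sub) == r]
      clf <- .trainOvr(.featMatrix(tr), aimDirection(tr), cost = cost)
      pred <- predictDirections(clf, te)
      .wrap180(pred - aimDirection(te))
    }))
  } else {
    tr <- .subsetPosture(x, trainPosture)
    te <- .subsetPosture(x, testPosture)
    if (ncol(tr) == 0L || ncol(te) == 0L)
      .stopf("design error: both postures must be present")
    pred <- predictDirections(trainDirectionClassifier(tr, cost = cost), te)
    offs <- .wrap180(pred - aimDirection(te))
  }
  .profileFromOffsets(offs, trainPosture, testPosture)
}

#' Pool generalization profiles
#'
#' Averages profiles weighted by their number of test predictions. Useful
#' for aggregating across participants or, with care about the sign
#' convention, across transfer directions.
#'
#' @param profiles a list of \linkS4class{GeneralizationProfile} objects
#'   with identical offset bins.
#' @return A pooled \linkS4class{GeneralizationProfile}.
#' @export
poolProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  bins <- profiles[[1]]@offsets
  w <- vapply(profiles, function(p) as.numeric(p@nTest), numeric(1))
  fr <- vapply(profiles, function(p) {
    if (!identical(p@offsets, bins)) .stopf("profiles have different bins")
    p@fraction
  }, numeric(length(bins)))
  new("GeneralizationProfile", offsets = bins,
      fraction = drop(fr %*% w) / sum(w),
      trainPosture = paste(unique(vapply(profiles, slot, "", "trainPosture")),
                           collapse = "+"),
      testPosture = paste(unique(vapply(profiles, slot, "", "testPosture")),
                          collapse = "+"),
      nTest = as.integer(sum(w)))
}

#' Asymmetry index of a generalization profile
#'
#' The mean predicted-label fraction over the positive offsets (+45, +90,
#' +135 degrees) minus that over the negative offsets (-45, -90, -135); the
#' 0-degree bin (the peak) and the 180-degree bin are excluded. A nonzero
#' index indicates a posture-induced rotation of the decoder's tuning.
#'
#' @param profile a \linkS4class{GeneralizationProfile}.
#' @return The index, a unitless value in [-1, 1].
#' @export
asymmetryIndex <- function(profile) {
  stopifnot(is(profile, "GeneralizationProfile"))
  pos <- profile@fraction[profile@offsets %in% c(45, 90, 135)]
  neg <- profile@fraction[profile@offsets %in% c(-45, -90, -135)]
  mean(pos) - mean(neg)
}

#' Paired contrast of asymmetry indices across participants
#'
#' Paired t-test of (across - within) per participant, Bonferroni-corrected
#' by the stated number of comparisons. When the paired differences have
#' zero variance the t statistic is degenerate: the result is flagged and
#' the p-value is 1 for identical lists and 0 for a constant nonzero shift.
#'
#' @param within,across equal-length numeric vectors of per-participant
#'   indices (n >= 3).
#' @param nComparisons Bonferroni correction factor.
#' @return An \linkS4class{AsymmetryResult}.
#' @export
asymmetryContrast <- function(within, across, nComparisons = 1L) {
  if (length(within) != length(across))
    .stopf("pairing error: lists have lengths %d and %d",
           length(within), length(across))
  if (length(within) < 3L)
    .stopf("size error: need at least 3 paired participants")
  d <- across - within
  if (stats::sd(d) == 0) {
    pRaw <- if (mean(d) == 0) 1 else 0
    res <- new("AsymmetryResult", withinByParticipant = within,
               acrossByParticipant = across, indexWithin = mean(within),
               indexAcross = mean(across), difference = mean(d),
               statistic = NA_real_, df = length(d) - 1,
               pValueRaw = pRaw,
               pValue = min(1, pRaw * nComparisons),
               nComparisons = as.integer(nComparisons), degenerate = TRUE)
    return(res)
  }
  tt <- stats::t.test(across, within, paired = TRUE)
  new("AsymmetryResult", withinByParticipant = within,
      acrossByParticipant = across, indexWithin = mean(within),
      indexAcross = mean(across), difference = mean(d),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      pValueRaw = tt$p.value,
      pValue = min(1, tt$p.value * nComparisons),
      nComparisons = as.integer(nComparisons), degenerate = FALSE)
}
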