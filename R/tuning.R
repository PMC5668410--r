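#' Fit a cosine tuning function
#'
#' Least-squares fit of \eqn{f(\theta) = k\cos(\theta - \mu) + b} via the
#' exact linear reparameterization
#' \eqn{f = A\cos\theta + B\sin\theta + b}, with
#' \eqn{k = \sqrt{A^2 + B^2}} and \eqn{\mu = \mathrm{atan2}(B, A)}; no
#' iterative optimizer is involved, so the fit is exact and deterministic.
#' The amplitude is nonnegative by construction (the sign is absorbed into
#' \eqn{\mu}). When the fitted amplitude falls below 1e-9 of the response
#' scale the fit is flagged untuned and \eqn{\mu} is undefined.
#'
#' @param directions stimulus directions in degrees; at least 3 distinct
#'   values are required.
#' @param responses numeric responses, same length.
#' @return A \linkS4class{CosineFit}.
#' @examples
#' th <- seq(0, 315, by = 45)
#' fitCosine(th, 2 + cos(pi / 180 * (th - 45)))
#' @export
fitCosine <- function(directions, responses) {
  if (length(directions) != length(responses))
    .stopf("directions and responses must have equal length")
  ok <- is.finite(directions) & is.finite(responses)
  directions <- directions[ok]; responses <- responses[ok]
  if (length(unique(.wrap360(directions))) < 3L)
    .stopf("insufficient design: need >= 3 distinct directions")
  X <- cbind(cosd = .cosd(directions), sind = .sind(directions), b = 1)
  fit <- stats::lm.fit(X, responses)
  A <- fit$coefficients[["cosd"]]
  B <- fit$coefficients[["sind"]]
  b <- fit$coefficients[["b"]]
  k <- sqrt(A^2 + B^2)
  floorVal <- 1e-9 * max(abs(responses), 1e-300)
  untuned <- k < floorVal
  new("CosineFit",
      k = if (untuned) 0 else k,
      mu = if (untuned) NA_real_ else .wrap360(.rad2deg(atan2(B, A))),
      b = b, rss = sum(fit$residuals^2), n = length(responses),
      untuned = untuned)
}

#' Signed preferred-direction shift between two postures
#'
#' Circular difference of the two preferred directions, wrapped to
#' (-180, 180] and reported clockwise-positive: a clockwise rotation of the
#' preferred direction from Pro to Mid yields a positive shift.
#'
#' @param fitPro,fitMid \linkS4class{CosineFit} objects for the Pro and Mid
#'   conditions; both must be tuned.
#' @return The shift in degrees in (-180, 180].
#' @examples
#' pro <- fitCosine(seq(0, 315, 45), cos(pi / 180 * seq(0, 315, 45)))
#' mid <- fitCosine(seq(0, 315, 45), cos(pi / 180 * (seq(0, 315, 45) - 300)))
#' pdShift(pro, mid)  # PD moved from 0 to 300: clockwise 60
#' @export
pdShift <- function(fitPro, fitMid) {
  stopifnot(is(fitPro, "CosineFit"), is(fitMid, "CosineFit"))
  if (fitPro@untuned || fitMid@untuned)
    .stopf("untuned input: preferred direction undefined")
  .wrap180(fitPro@mu - fitMid@mu)
}

# Mean direction (degrees) and resultant length of a set of angles.
.circMean <- function(angles) {
  C <- mean(.cosd(angles)); S <- mean(.sind(angles))
  list(mean = .wrap360(.rad2deg(atan2(S, C))), R = sqrt(C^2 + S^2))
}

# Bootstrap mean directions (degrees), B resamples, deterministic under seed.
.bootMeans <- function(angles, B, seed) {
  n <- length(angles)
  cosd <- .cosd(angles); sind <- .sind(angles)
  .withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    C <- rowMeans(matrix(cosd[idx], nrow = B))
    S <- rowMeans(matrix(sind[idx], nrow = B))
    .wrap360(.rad2deg(atan2(S, C)))
  })
}

#' Circular mean direction with a 95 percent confidence interval
#'
#' The mean direction is the argument of the mean resultant vector. The CI
#' halfwidth uses the standard dispersion-based large-sample formula for the
#' mean direction; when the resultant length is too small for that closed
#' form (the asin argument leaves [0, 1]), a seeded bootstrap percentile CI
#' is used instead.
#'
#' @param angles angles in degrees, n >= 2.
#' @param confidence confidence level, default 0.95.
#' @param bootstrap number of bootstrap resamples for the fallback.
#' @param bootSeed seed for the bootstrap fallback.
#' @return A \linkS4class{CircularSummary}.
#' @examples
#' circularMeanCI(c(50, 60, 55, 65, 58, 62))
#' @export
circularMeanCI <- function(angles, confidence = 0.95, bootstrap = 10000L,
                           bootSeed = 1L) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2L) .stopf("size error: need at least 2 angles, got %d", n)
  cm <- .circMean(angles)
  if (cm$R < 1e-12) .stopf("undefined mean: zero resultant vector")
  rho2 <- mean(.cosd(2 * (angles - cm$mean)))
  disp <- (1 - rho2) / (2 * cm$R^2)
  se <- sqrt(disp / n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  arg <- z * se
  if (is.finite(arg) && arg < 1) {
    ci <- .rad2deg(asin(arg))
    method <- "fisher"
  } else {
    d <- abs(.wrap180(.bootMeans(angles, bootstrap, bootSeed) - cm$mean))
    ci <- as.numeric(stats::quantile(d, confidence, names = FALSE))
    method <- "bootstrap"
  }
  new("CircularSummary", meanAngle = cm$mean, ciHalfwidth = ci,
      resultantLength = min(cm$R, 1), n = as.integer(n),
      confidence = confidence, method = method)
}

#' One-sample test of a circular mean direction against a reference
#'
#' Tests whether the population mean direction equals \code{reference}. The
#' p-value is a seeded bootstrap sign-type p-value: resampled mean directions
#' are compared to the reference and the smaller tail fraction is doubled
#' (with add-one smoothing). A CI-inclusion decision (reference outside the
#' (1 - alpha) CI of the mean direction implies rejection) is reported
#' alongside, so the exact method is recorded in the output.
#'
#' @param angles angles in degrees, n >= 3.
#' @param reference reference direction in degrees.
#' @param confidence confidence level of the companion CI.
#' @param bootstrap number of bootstrap resamples.
#' @param bootSeed seed.
#' @return A list with elements \code{pValue}, \code{meanAngle},
#'   \code{ciHalfwidth}, \code{ciContainsReference}, \code{n},
#'   \code{reference} and \code{method}.
#' @examples
#' circularOneSampleTest(c(85, 95, 90, 88, 92, 91), reference = 0)$pValue
#' @export
circularOneSampleTest <- function(angles, reference, confidence = 0.95,
                                  bootstrap = 10000L, bootSeed = 1L) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 3L) .stopf("size error: need at least 3 angles, got %d", n)
  cm <- .circMean(angles)
  if (cm$R < 1e-12) .stopf("undefined mean: zero resultant vector")
  d <- .wrap180(.bootMeans(angles, bootstrap, bootSeed) - reference)
  nle <- sum(d <= 0); nge <- sum(d >= 0)
  p <- min(1, 2 * (min(nle, nge) + 1) / (bootstrap + 1))
  cs <- circularMeanCI(angles, confidence = confidence,
                       bootstrap = bootstrap, bootSeed = bootSeed)
  list(pValue = p, meanAngle = cm$mean, ciHalfwidth = cs@ciHalfwidth,
       ciContainsReference =
         abs(.wrap180(cm$mean - reference)) <= cs@ciHalfwidth,
       n = n, reference = reference,
       method = "bootstrap sign test with CI inclusion")
}

#' Fit per-muscle cosine tuning and posture-induced PD shifts
#'
#' For each muscle in an EMG trial table, averages activation per direction
#' and posture, fits the cosine tuning model under each posture, and
#' computes the clockwise-positive preferred-direction shift from Pro to
#' Mid. A circular summary of the shifts across muscles defines the
#' muscle-like coordinate frame.
#'
#' @param emg a data.frame as returned by \code{\link{generateEmg}} (columns
#'   muscle_id, posture, direction_deg, activation).
#' @param confidence confidence level of the group summary.
#' @return A list with \code{fits} (data.frame: muscle, posture, k, mu, b,
#'   rss, n), \code{shifts} (named numeric, degrees), and \code{summary} (a
#'   \linkS4class{CircularSummary} across muscles; NULL when fewer than 2
#'   muscles).
#' @export
fitEmgTuning <- function(emg, confidence = 0.95) {
  need <- c("muscle_id", "posture", "direction_deg", "activation")
  miss <- setdiff(need, colnames(emg))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  muscles <- unique(emg$muscle_id)
  fits <- list(); shifts <- numeric(0)
  rows <- list()
  for (m in muscles) {
    fm <- list()
    for (p in c("Pro", "Mid")) {
      sub <- emg[emg$muscle_id == m & emg$posture == p, ]
      agg <- stats::aggregate(activation ~ direction_deg, data = sub, FUN = mean)
      fm[[p]] <- fitCosine(agg$direction_deg, agg$activation)
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = m, posture = p, k = fm[[p]]@k, mu = fm[[p]]@mu,
        b = fm[[p]]@b, rss = fm[[p]]@rss, n = fm[[p]]@n,
        stringsAsFactors = FALSE)
    }
    shifts[m] <- pdShift(fm$Pro, fm$Mid)
  }
  summary <- if (length(shifts) >= 2L)
    circularMeanCI(shifts, confidence = confidence) else NULL
  list(fits = do.call(rbind, rows), shifts = shifts, summary = summary)
}
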