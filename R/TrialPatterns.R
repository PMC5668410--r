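#' Construct a TrialPatterns container
#'
#' @param responses numeric matrix, samples x features (one row per trial or
#'   task volume). Stored internally as features x samples.
#' @param direction numeric vector of aiming labels in degrees, one per sample.
#' @param posture character vector ("Pro"/"Mid"), one per sample (recycled if
#'   length 1).
#' @param run integer run identifiers, one per sample.
#' @param participant integer participant identifiers (recycled if length 1).
#'
#' @return A \linkS4class{TrialPatterns} object.
#' @examples
#' x <- TrialPatterns(matrix(rnorm(16), 4, 4), direction = c(0, 90, 180, 270),
#'                    posture = "Pro", run = c(1, 1, 2, 2), participant = 1)
#' aimDirection(x)
#' @export
TrialPatterns <- function(responses, direction, posture, run, participant = 1L) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (length(direction) != n)
    .stopf("need one direction label per sample (%d samples, %d labels)",
           n, length(direction))
  posture <- rep_len(as.character(posture), n)
  run <- rep_len(as.integer(run), n)
  participant <- rep_len(as.integer(participant), n)
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("v%04d", seq_len(ncol(responses)))
  se <- SummarizedExperiment(
    assays = list(responses = t(responses)),
    colData = DataFrame(direction_deg = as.numeric(direction),
                        posture = posture, run_id = run,
                        participant_id = participant)
  )
  new("TrialPatterns", se)
}

#' @rdname TrialPatterns-accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname TrialPatterns-accessors
#' @export
setGeneric("aimDirection", function(x) standardGeneric("aimDirection"))

#' @rdname TrialPatterns-accessors
#' @export
setGeneric("posture", function(x) standardGeneric("posture"))

#' @rdname TrialPatterns-accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname TrialPatterns-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' Accessors for TrialPatterns
#'
#' \code{responses} returns the samples x features matrix;
#' \code{aimDirection}, \code{posture}, \code{runId} and
#' \code{participantId} return per-sample metadata.
#'
#' @param x a \linkS4class{TrialPatterns} object.
#' @return A matrix for \code{responses}; vectors otherwise.
#' @name TrialPatterns-accessors
NULL

#' @rdname TrialPatterns-accessors
#' @export
setMethod("responses", "TrialPatterns", function(x) t(assay(x, "responses")))

#' @rdname TrialPatterns-accessors
#' @export
setMethod("aimDirection", "TrialPatterns", function(x) colData(x)$direction_deg)

#' @rdname TrialPatterns-accessors
#' @export
setMethod("posture", "TrialPatterns", function(x) colData(x)$posture)

#' @rdname TrialPatterns-accessors
#' @export
setMethod("runId", "TrialPatterns", function(x) colData(x)$run_id)

#' @rdname TrialPatterns-accessors
#' @export
setMethod("participantId", "TrialPatterns", function(x) colData(x)$participant_id)

# Subset to one posture (internal).
.subsetPosture <- function(x, post) x[, posture(x) == post]

# Samples x features matrix for a subset of columns (internal).
.featMatrix <- function(x) t(assay(x, "responses"))
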