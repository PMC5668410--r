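#' Write trial patterns as a delimited text table
#'
#' One row per sample with header columns participant_id, run_id, posture,
#' direction_deg followed by the feature columns (v0001, ...).
#'
#' @param x a \linkS4class{TrialPatterns}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrialPatterns <- function(x, path) {
  stopifnot(is(x, "TrialPatterns"))
  df <- data.frame(participant_id = participantId(x), run_id = runId(x),
                   posture = posture(x), direction_deg = aimDirection(x),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(.featMatrix(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read trial patterns from a delimited text table
#'
#' @param path TSV path as written by \code{\link{writeTrialPatterns}}.
#' @return A \linkS4class{TrialPatterns}.
#' @export
readTrialPatterns <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("participant_id", "run_id", "posture", "direction_deg")
  miss <- setdiff(meta, colnames(df))
  if (length(miss))
    .stopf("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  feats <- setdiff(colnames(df), meta)
  TrialPatterns(as.matrix(df[, feats, drop = FALSE]),
                direction = df$direction_deg, posture = df$posture,
                run = df$run_id, participant = df$participant_id)
}

#' Write an EMG trial table
#' @param emg data.frame from \code{\link{generateEmg}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEmg <- function(emg, path) {
  utils::write.table(emg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EMG trial table
#' @param path TSV path.
#' @return A data.frame.
#' @export
readEmg <- function(path) utils::read.delim(path)
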