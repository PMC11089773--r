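#' Read scored labels from a TSV/CSV file
#'
#' Expects a header row with columns \code{score} (numeric) and
#' \code{label} (0/1), plus an optional \code{id} column. The field
#' separator (tab or comma) is sniffed from the header line. Lines starting
#' with \code{#} are ignored. Row order is preserved, which matters only
#' for deliberately order-sensitive emulation profiles.
#'
#' @param path path to the file.
#' @return A \code{\linkS4class{ScoredLabels}} object.
#' @details Malformed rows are reported with their line number in the file.
#' @export
readScores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  if (length(lineNo) < 2L) stop("file has no data rows: ", path)
  header <- lines[lineNo[1]]
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  cols <- trimws(strsplit(header, sep, fixed = TRUE)[[1]])
  iScore <- match("score", cols)
  iLabel <- match("label", cols)
  iId <- match("id", cols)
  if (is.na(iScore) || is.na(iLabel))
    stop("missing required column(s) 'score' and/or 'label' in ", path)
  dataNo <- lineNo[-1]
  fields <- strsplit(lines[dataNo], sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < max(iScore, iLabel))
  if (length(bad))
    stop(sprintf("line %d: expected at least %d fields, found %d",
                 dataNo[bad[1]], max(iScore, iLabel), nf[bad[1]]))
  scoreTxt <- vapply(fields, `[`, character(1), iScore)
  labelTxt <- vapply(fields, `[`, character(1), iLabel)
  scores <- suppressWarnings(as.numeric(scoreTxt))
  badS <- which(!is.finite(scores))
  if (length(badS))
    stop(sprintf("line %d: non-numeric or non-finite score '%s'",
                 dataNo[badS[1]], scoreTxt[badS[1]]))
  labelOk <- trimws(labelTxt) %in% c("0", "1")
  if (any(!labelOk)) {
    i <- which(!labelOk)[1]
    stop(sprintf("line %d: label must be 0 or 1, found '%s'",
                 dataNo[i], labelTxt[i]))
  }
  labels <- as.integer(trimws(labelTxt))
  ids <- if (!is.na(iId)) vapply(fields, `[`, character(1), iId)
         else character(0)
  ScoredLabels(scores, labels, ids)
}

#' Write scored labels to a TSV file
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(data, path) {
  df <- data.frame(score = scoreValues(data), label = trueLabels(data))
  if (length(entityIds(data)))
    df <- cbind(id = entityIds(data), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sampled curve points to a TSV file
#'
#' @param curve a \code{\linkS4class{PRCurve}}.
#' @param path output path.
#' @param pointsPerSegment,dropAnchors passed to \code{\link{curvePoints}}.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path, pointsPerSegment = 64,
                       dropAnchors = FALSE) {
  pts <- curvePoints(curve, pointsPerSegment, dropAnchors)
  utils::write.table(format(pts, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Numeric results are written at full precision; the configuration block
#' (methods, start convention, step, package version) is always embedded so
#' published values can be attributed to a specific computation method.
#'
#' @param report an \code{\linkS4class{EvaluationReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readReport}}
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  x <- list(profile = report@profile, auprc = report@auprc,
            auroc = report@auroc, baseline = report@baseline,
            method = list(no_tie = report@noTieMethod,
                          tie = report@tieMethod,
                          start_convention = report@startConvention,
                          step = report@step),
            issues = report@issues, n_pos = report@nPos,
            n_neg = report@nNeg, n_anchors = report@nAnchors,
            version = report@version)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an evaluation report back from JSON
#'
#' @param path path written by \code{\link{writeReport}}.
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EvaluationReport", profile = x$profile,
      noTieMethod = x$method$no_tie, tieMethod = x$method$tie,
      startConvention = x$method$start_convention,
      step = as.numeric(x$method$step),
      auprc = as.numeric(x$auprc), auroc = as.numeric(x$auroc),
      baseline = as.numeric(x$baseline),
      issues = as.character(unlist(x$issues)),
      nPos = as.integer(x$n_pos), nNeg = as.integer(x$n_neg),
      nAnchors = as.integer(x$n_anchors), version = x$version)
}

#' Rescale scores to (0, 1) preserving order
#'
#' Convenience for tools that require scores inside the unit interval: a
#' strictly increasing affine map of the scores onto [0, 1]. Anchor points
#' and every AUPRC/AUROC value are invariant under such a map.
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object.
#' @return A rescaled \code{\linkS4class{ScoredLabels}} object.
#' @export
rescale01 <- function(data) {
  s <- scoreValues(data)
  rng <- range(s)
  s <- if (rng[1] == rng[2]) rep(0.5, length(s))
       else (s - rng[1]) / (rng[2] - rng[1])
  ScoredLabels(s, trueLabels(data), entityIds(data))
}
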