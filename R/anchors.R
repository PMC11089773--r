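#' Construct a ScoredLabels object
#'
#' @param scores numeric vector of finite classification scores. Ties are
#'   allowed and are meaningful: all entities sharing a score form one tie
#'   group and define a single anchor point.
#' @param labels ground-truth class per entity: integers in \{0, 1\} or a
#'   logical vector (\code{TRUE} = actual positive). Any other encoding is
#'   rejected rather than coerced.
#' @param ids optional character vector of entity identifiers.
#'
#' @return A \code{\linkS4class{ScoredLabels}} object.
#'
#' @details Score equality is exact floating-point equality; no
#' epsilon-based tie merging is performed, so tie semantics are
#' deterministic and independent of input order. Round scores beforehand
#' (e.g. with \code{round()}) if coarser tie granularity is wanted.
#'
#' @examples
#' sl <- ScoredLabels(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))
#' nPos(sl)
#' @export
ScoredLabels <- function(scores, labels, ids = character(0)) {
  if (!is.numeric(scores))
    stop("scores must be numeric")
  if (is.logical(labels)) {
    labels <- as.integer(labels)
  } else if (is.numeric(labels)) {
    if (any(is.na(labels)) || any(!labels %in% c(0, 1)))
      stop("labels must be 0/1 or logical; other encodings are not coerced")
    labels <- as.integer(labels)
  } else {
    stop("labels must be 0/1 or logical; other encodings are not coerced")
  }
  if (any(!is.finite(scores)))
    stop("non-finite score")
  new("ScoredLabels", scores = as.numeric(scores), labels = labels,
      ids = as.character(ids))
}

#' Accessors for ScoredLabels
#'
#' @param x a \code{\linkS4class{ScoredLabels}} object.
#' @return \code{scoreValues}: the numeric score vector; \code{trueLabels}:
#'   the 0/1 integer label vector; \code{entityIds}: identifiers (possibly
#'   empty); \code{nPos}/\code{nNeg}: class counts P and N;
#'   \code{prevalence}: P/(P+N), the AUPRC of a no-skill classifier and the
#'   floor against which reported AUPRC values should be judged.
#' @name accessors
#' @aliases scoreValues trueLabels entityIds nPos nNeg prevalence
NULL

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoredLabels", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("trueLabels", "ScoredLabels", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("entityIds", "ScoredLabels", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("nPos", "ScoredLabels", function(x) sum(x@labels == 1L))

#' @rdname accessors
#' @export
setMethod("nNeg", "ScoredLabels", function(x) sum(x@labels == 0L))

#' @rdname accessors
#' @export
setMethod("prevalence", "ScoredLabels",
          function(x) sum(x@labels == 1L) / length(x@labels))

setMethod("show", "ScoredLabels", function(object) {
  cat(sprintf("ScoredLabels: %d entities (%d positive, %d negative)\n",
              length(object@scores), nPos(object), nNeg(object)))
  u <- length(unique(object@scores))
  cat(sprintf("  %d unique scores (%s)\n", u,
              if (u == length(object@scores)) "no ties" else "ties present"))
})

#' Length of a ScoredLabels object
#' @param x a ScoredLabels object.
#' @return the number of entities.
#' @export
setMethod("length", "ScoredLabels", function(x) length(x@scores))

#' Construct a single tie group
#'
#' Convenience constructor used mainly for studying one curve segment in
#' isolation (see \code{\link{connectSegment}}).
#'
#' @param tpFrom,fpFrom cumulative true/false positive counts at the
#'   higher-score flanking anchor; both 0 for a group starting at the
#'   virtual origin.
#' @param dtp,dfp positives/negatives contributed by the group.
#' @param nPos total number of actual positives (recall denominator).
#' @return A \code{\linkS4class{TieGroup}} object.
#' @examples
#' g <- tieGroup(tpFrom = 1, fpFrom = 0, dtp = 2, dfp = 1, nPos = 4)
#' connectSegment(g, "continuous_expectation")$area
#' @export
tieGroup <- function(tpFrom, fpFrom, dtp, dfp, nPos) {
  new("TieGroup", tpFrom = as.integer(tpFrom), fpFrom = as.integer(fpFrom),
      dtp = as.integer(dtp), dfp = as.integer(dfp), nPos = as.integer(nPos))
}

#' Compute anchor points and tie groups
#'
#' Each unique classification score observed is used as a threshold: all
#' entities with a score greater than or equal to the threshold are
#' predicted positive, yielding one (recall, precision) anchor point per
#' unique score. Entities sharing a score form a tie group contributing
#' (dTP, dFP) between adjacent anchors. Grouping is by score value, never
#' by row position, so the result is invariant to the order of the input
#' rows.
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object with at least one
#'   actual positive.
#'
#' @return A list with components
#'   \item{anchors}{data.frame with columns \code{threshold}, \code{tp},
#'     \code{fp}, \code{recall}, \code{precision}, in descending threshold
#'     order; the final row has \code{tp = P}, \code{fp = N} (recall 1).}
#'   \item{groups}{data.frame with columns \code{tpFrom}, \code{fpFrom},
#'     \code{dtp}, \code{dfp}; row i is the increment from anchor i-1 (the
#'     virtual origin for i = 1) to anchor i.}
#'
#' @details The virtual origin (TP = FP = 0), where precision is 0/0, is
#' never emitted as an anchor point; how the curve is extended to recall 0
#' is a property of the connection method and start convention (see
#' \code{\link{buildPRCurve}}).
#'
#' @examples
#' ap <- computeAnchorPoints(ScoredLabels(c(.9, .8, .7, .6), c(1, 1, 0, 1)))
#' ap$anchors
#' @export
setMethod("computeAnchorPoints", "ScoredLabels", function(data) {
  P <- nPos(data)
  if (P == 0L) stop("no positive entities")
  ord <- order(data@scores, decreasing = TRUE, method = "radix")
  s <- data@scores[ord]
  l <- data@labels[ord]
  isNew <- !duplicated(s)
  grp <- cumsum(isNew)
  dtp <- as.integer(rowsum(l, grp, reorder = FALSE))
  size <- tabulate(grp)
  dfp <- size - dtp
  tp <- cumsum(dtp)
  fp <- cumsum(dfp)
  anchors <- data.frame(threshold = s[isNew], tp = tp, fp = fp,
                        recall = tp / P, precision = tp / (tp + fp))
  groups <- data.frame(tpFrom = c(0L, tp[-length(tp)]),
                       fpFrom = c(0L, fp[-length(fp)]),
                       dtp = dtp, dfp = dfp)
  list(anchors = anchors, groups = groups)
})

#' Confusion matrix at a fixed threshold
#'
#' Entities with \code{score >= t} are predicted positive (inclusive
#' threshold rule, the same coordinate convention anchor points use).
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object.
#' @param t finite numeric threshold.
#' @return Named integer vector \code{c(TP, FP, FN, TN)}.
#' @examples
#' confusionAtThreshold(ScoredLabels(c(0.9, 0.1), c(1, 0)), 0.5)
#' @export
setMethod("confusionAtThreshold", "ScoredLabels", function(data, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("threshold must be a single finite number")
  predPos <- data@scores >= t
  pos <- data@labels == 1L
  c(TP = sum(predPos & pos), FP = sum(predPos & !pos),
    FN = sum(!predPos & pos), TN = sum(!predPos & !pos))
})

#' Export anchor points as a TSV file
#'
#' @param x a \code{\linkS4class{ScoredLabels}} or
#'   \code{\linkS4class{PRCurve}} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnchors <- function(x, path) {
  anchors <- if (is(x, "PRCurve")) x@anchors
             else computeAnchorPoints(x)$anchors
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
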