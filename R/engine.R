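## Curve assembly: anchors + per-group connection method + start/coverage
## conventions -> PRCurve with exact AUPRC.

## methods: character vector, one connection method per group row.
## start: "derived" extends the curve to recall 0 with the method's own
##   limit; "fixed01" forces a (0, 1) start, emulated for the non-AP
##   methods as a straight chord from (0, 1) to the first anchor (the AP
##   step curve drops immediately, so its area is unchanged).
## fullCoverage = FALSE sets the upper integration bound at the last anchor
##   derived from observed scores instead of forcing a recall-1 terminal.
##   Under the inclusive >= threshold rule the final anchor already sits at
##   recall 1, so no area is removed here; the flag records the documented
##   convention and surfaces in issue reports.
.buildCurve <- function(anchors, groups, P, N, methods, step, start,
                        fullCoverage = TRUE, label = methods[1]) {
  k <- nrow(groups)
  stopifnot(length(methods) == k)
  pAnchor <- anchors$precision
  areas <- numeric(k)
  segMethod <- methods
  for (i in seq_len(k)) {
    g <- groups[i, ]
    if (i == 1L) {
      if (start == "fixed01" && methods[1L] != "ap") {
        areas[1L] <- .segmentArea("linear", 0L, 0L, g$dtp, g$dfp, P, step,
                                  pFrom = 1)
      } else {
        areas[1L] <- .segmentArea(methods[1L], 0L, 0L, g$dtp, g$dfp, P, step)
      }
    } else {
      areas[i] <- .segmentArea(methods[i], g$tpFrom, g$fpFrom, g$dtp, g$dfp,
                               P, step, pFrom = pAnchor[i - 1L])
    }
  }
  rFrom <- groups$tpFrom / P
  rTo <- (groups$tpFrom + groups$dtp) / P
  segs <- data.frame(method = segMethod,
                     tpFrom = groups$tpFrom, fpFrom = groups$fpFrom,
                     dtp = groups$dtp, dfp = groups$dfp,
                     rFrom = rFrom, rTo = rTo,
                     pFrom = c(NA_real_, pAnchor[-k]), pTo = pAnchor,
                     area = areas)
  new("PRCurve", anchors = anchors, segments = segs, method = label,
      step = step, startConvention = start, auprc = sum(areas),
      nPos = as.integer(P), nNeg = as.integer(N))
}

#' Build a precision-recall curve
#'
#' Computes the anchor points of \code{data} and connects them with one of
#' the four methods, applying the chosen start convention. The AUPRC is the
#' sum of the exact per-segment areas.
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object.
#' @param method connection method: \code{"linear"},
#'   \code{"discrete_expectation"}, \code{"continuous_expectation"} or
#'   \code{"ap"}. Applied uniformly to all tie groups (size-1 groups
#'   included), so the no-tie and tied regimes share one code path.
#' @param step discrete-expectation increment (ignored by other methods).
#' @param startConvention \code{"derived"} starts the curve at (0, p*)
#'   where p* is the method's own limit at recall 0 — the first tie group's
#'   precision for the expectation and AP methods, the first anchor's
#'   precision for the linear method. \code{"fixed01"} forces the start
#'   point (0, 1); this fabricates precision at a point where it is
#'   undefined and inflates the area whenever the first anchor's precision
#'   is below one.
#'
#' @return A \code{\linkS4class{PRCurve}} object.
#'
#' @details When the data contain no actual negatives the curve is the
#' constant line precision = 1 and AUPRC = 1 under all methods; this is
#' allowed with a warning. No actual positives is an error.
#'
#' @examples
#' sl <- ScoredLabels(rep(0.5, 74), rep(c(1, 0), c(32, 42)))
#' auprc(buildPRCurve(sl, "continuous_expectation"))  # prevalence 32/74
#' @export
setMethod("buildPRCurve", "ScoredLabels",
  function(data, method = "continuous_expectation", step = 1,
           startConvention = "derived") {
    method <- match.arg(method, .METHODS)
    startConvention <- match.arg(startConvention, c("derived", "fixed01"))
    if (method == "discrete_expectation" && step <= 0)
      stop("step must be positive")
    if (nNeg(data) == 0L)
      warning("no negative entities: precision is identically 1")
    ap <- computeAnchorPoints(data)
    .buildCurve(ap$anchors, ap$groups, nPos(data), nNeg(data),
                rep(method, nrow(ap$groups)), step, startConvention)
  })

#' Area under the precision-recall curve
#'
#' For a \code{\linkS4class{PRCurve}}, returns the stored sum of exact
#' segment areas. For a \code{\linkS4class{ScoredLabels}} object, builds
#' the curve first (arguments are passed to \code{\link{buildPRCurve}}).
#'
#' @param x a PRCurve or ScoredLabels object.
#' @param ... for ScoredLabels: \code{method}, \code{step},
#'   \code{startConvention}.
#' @return a single numeric value in [0, 1].
#' @examples
#' sl <- ScoredLabels(c(.9, .8, .7), c(1, 0, 1))
#' auprc(sl, method = "ap")  # 5/6
#' @export
setMethod("auprc", "PRCurve", function(x, ...) x@auprc)

#' @rdname auprc
#' @export
setMethod("auprc", "ScoredLabels",
          function(x, ...) buildPRCurve(x, ...)@auprc)

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve with tie groups handled by the
#' diagonal chord: each group of tied scores contributes
#' dFP * (TP_prev + dTP/2) / (P * N). This equals the Mann-Whitney U
#' statistic with half credit for tied score pairs, divided by P * N —
#' the convention on which the surveyed AUPRC tools largely agree, which is
#' why AUROC serves as the cross-tool reference value. It does not depend
#' on which PR tie method is configured.
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object with at least one
#'   positive and one negative.
#' @return a single numeric value in [0, 1].
#' @examples
#' auroc(ScoredLabels(c(.9, .8, .7), c(1, 1, 0)))  # perfect separation
#' @export
setMethod("auroc", "ScoredLabels", function(data) {
  P <- nPos(data); N <- nNeg(data)
  if (P == 0L) stop("no positive entities")
  if (N == 0L) stop("no negative entities")
  g <- computeAnchorPoints(data)$groups
  sum(g$dfp * (g$tpFrom + g$dtp / 2)) / (P * N)
})

#' Points realized on a PR curve
#'
#' Samples the curve's segments for plotting, export, or numerical
#' integration checks. Linear and AP segments are exact polylines; discrete
#' expectation segments return their interpolated vertices; continuous
#' expectation segments are sampled at \code{pointsPerSegment} points.
#'
#' @param x a \code{\linkS4class{PRCurve}}.
#' @param pointsPerSegment sampling density for continuous segments.
#' @param dropAnchors if \code{TRUE}, keep only each segment's right anchor
#'   (reproducing the visualization defect of tools that omit anchor points
#'   from the plotted curve; areas are never affected).
#' @return a data.frame with columns \code{recall}, \code{precision}.
#' @export
setMethod("curvePoints", "PRCurve",
  function(x, pointsPerSegment = 64, dropAnchors = FALSE) {
    segs <- x@segments
    P <- x@nPos
    out <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      if (s$method == "omitted") next
      m <- s$method
      pFrom <- s$pFrom
      if (i == 1L) {
        if (x@startConvention == "fixed01") {
          pFrom <- 1
          if (m != "ap") m <- "linear"
        } else pFrom <- NA_real_
      }
      pts <- .segmentPoints(m, s$tpFrom, s$fpFrom, s$dtp, s$dfp, P,
                            x@step, pFrom, n = pointsPerSegment)
      if (dropAnchors)
        pts <- pts[nrow(pts), , drop = FALSE]
      out[[i]] <- pts
    }
    pts <- do.call(rbind, out)
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    data.frame(recall = pts[keep, 1], precision = pts[keep, 2])
  })

#' @rdname curve-accessors
#' @export
setMethod("anchorTable", "PRCurve", function(x) x@anchors)

#' Accessors for PRCurve
#'
#' @param x a \code{\linkS4class{PRCurve}}.
#' @return \code{anchorTable}: the anchor-point data.frame;
#'   \code{segmentTable}: the per-tie-group segment data.frame with exact
#'   areas.
#' @name curve-accessors
#' @aliases anchorTable segmentTable
#' @export
setMethod("segmentTable", "PRCurve", function(x) x@segments)

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: method = %s, start = %s\n",
              object@method, object@startConvention))
  cat(sprintf("  %d anchor points, %d segments; P = %d, N = %d\n",
              nrow(object@anchors), nrow(object@segments),
              object@nPos, object@nNeg))
  cat(sprintf("  AUPRC = %.3f (baseline %.3f)\n", object@auprc,
              object@nPos / (object@nPos + object@nNeg)))
})

#' Plot a PR curve
#'
#' @param x a \code{\linkS4class{PRCurve}}.
#' @param y ignored.
#' @param ... passed to \code{plot.default}.
#' @export
setMethod("plot", signature(x = "PRCurve", y = "missing"),
  function(x, y, ...) {
    pts <- curvePoints(x, pointsPerSegment = 256)
    graphics::plot(pts$recall, pts$precision, type = "l",
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("%s (AUPRC = %.3f)", x@method, x@auprc),
                   ...)
    graphics::points(x@anchors$recall, x@anchors$precision, pch = 19,
                     cex = 0.6)
    graphics::abline(h = x@nPos / (x@nPos + x@nNeg), lty = 3)
    invisible(x)
  })
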