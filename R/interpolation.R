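## Segment-level machinery for the four anchor-connection methods.
##
## Every method is expressed per tie group. A group contributes dtp true
## positives and dfp false positives between the flanking anchors; recall
## moves by dtp / P. No-tie data is the special case where every group has
## size 1, so the same code path serves both regimes.

.METHODS <- c("linear", "discrete_expectation", "continuous_expectation", "ap")

#' Expected precision while traversing a tie group
#'
#' Under the assumption that all orderings of the entities sharing one
#' classification score are equally likely, the expected precision after
#' absorbing x of the group's dtp true positives (and proportionally
#' s = dfp/dtp of its false positives) is
#' \deqn{p(x) = \frac{TP_A + x}{TP_A + FP_A + (1 + s)x}, \quad x \in [0, dtp]}
#' where (TP_A, FP_A) are the cumulative counts at the higher-score flanking
#' anchor. Both expectation connection methods evaluate this function; the
#' discrete variant samples it at increments of \code{step}, the continuous
#' variant integrates it exactly.
#'
#' From the virtual origin (TP_A = FP_A = 0) the function is constant at
#' the group's own precision dtp / (dtp + dfp).
#'
#' @param group a \code{\linkS4class{TieGroup}}.
#' @param x numeric vector of true-positive increments in [0, dtp].
#' @return numeric vector of expected precisions.
#' @export
expectationPrecision <- function(group, x) {
  stopifnot(is(group, "TieGroup"))
  tpA <- group@tpFrom; fpA <- group@fpFrom
  dtp <- group@dtp; dfp <- group@dfp
  if (any(x < -1e-12 | x > dtp + 1e-12))
    stop("x outside [0, dtp]")
  if (tpA + fpA == 0L)
    return(rep(dtp / (dtp + dfp), length(x)))
  if (dtp == 0L)
    return(rep(tpA / (tpA + fpA), length(x)))
  s <- dfp / dtp
  (tpA + x) / (tpA + fpA + (1 + s) * x)
}

## Exact area (in recall space) of one segment under one method.
## pFrom is the precision at the left end; NA marks a group starting at the
## virtual origin, where each method supplies its own start value.
.segmentArea <- function(method, tpA, fpA, dtp, dfp, P, step = 1,
                         pFrom = NA_real_) {
  if (dtp == 0L) return(0)
  dr <- dtp / P
  pTo <- (tpA + dtp) / (tpA + dtp + fpA + dfp)
  fromOrigin <- (tpA + fpA == 0L)
  switch(method,
    linear = {
      if (fromOrigin && is.na(pFrom)) pFrom <- pTo  # derived start
      dr * (pFrom + pTo) / 2
    },
    ap = dr * pTo,
    discrete_expectation = {
      if (step <= 0) stop("step must be positive")
      if (fromOrigin) return(dr * pTo)  # constant expectation from origin
      xs <- seq(0, dtp, by = step)
      if (xs[length(xs)] < dtp) xs <- c(xs, dtp)
      s <- dfp / dtp
      ys <- (tpA + xs) / (tpA + fpA + (1 + s) * xs)
      sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) / P
    },
    continuous_expectation = {
      if (fromOrigin) return(dr * pTo)  # constant expectation from origin
      ## closed form of (1/P) * int_0^dtp (tpA + x) / (a x + b) dx
      ## with a = 1 + dfp/dtp, b = tpA + fpA > 0
      a <- 1 + dfp / dtp
      b <- tpA + fpA
      (dtp / a + (tpA - b / a) * log1p(a * dtp / b) / a) / P
    },
    stop("unknown method: ", method)
  )
}

## Realized (recall, precision) vertices of one segment, for plotting and
## for dense numerical cross-checks. `n` controls sampling density of the
## continuous curve only; linear/ap/discrete segments are exact polylines.
.segmentPoints <- function(method, tpA, fpA, dtp, dfp, P, step = 1,
                           pFrom = NA_real_, n = 64) {
  rFrom <- tpA / P
  if (dtp == 0L) {
    pTo <- if (tpA + fpA + dfp > 0) tpA / (tpA + fpA + dfp) else NA_real_
    pA <- if (tpA + fpA > 0) tpA / (tpA + fpA) else pTo
    return(cbind(recall = c(rFrom, rFrom), precision = c(pA, pTo)))
  }
  dr <- dtp / P
  rTo <- rFrom + dr
  pTo <- (tpA + dtp) / (tpA + dtp + fpA + dfp)
  fromOrigin <- (tpA + fpA == 0L)
  grp <- tieGroup(tpA, fpA, dtp, dfp, P)
  switch(method,
    linear = {
      if (fromOrigin && is.na(pFrom)) pFrom <- pTo
      cbind(recall = c(rFrom, rTo), precision = c(pFrom, pTo))
    },
    ap = {
      if (is.na(pFrom))
        cbind(recall = c(rFrom, rTo), precision = c(pTo, pTo))
      else  # step discontinuity at the left anchor
        cbind(recall = c(rFrom, rFrom, rTo), precision = c(pFrom, pTo, pTo))
    },
    discrete_expectation = {
      xs <- seq(0, dtp, by = step)
      if (xs[length(xs)] < dtp) xs <- c(xs, dtp)
      cbind(recall = rFrom + xs / P,
            precision = expectationPrecision(grp, xs))
    },
    continuous_expectation = {
      xs <- seq(0, dtp, length.out = max(2L, n))
      cbind(recall = rFrom + xs / P,
            precision = expectationPrecision(grp, xs))
    },
    stop("unknown method: ", method)
  )
}

#' Connect the flanking anchors of one tie group
#'
#' Produces the curve segment a given connection method draws across one
#' tie group, together with its exact area in recall space (the segment's
#' AUPRC contribution).
#'
#' @param group a \code{\linkS4class{TieGroup}}.
#' @param method one of \code{"linear"} (straight chord; trapezoid area —
#'   the variant known to be optimistic across tie groups),
#'   \code{"discrete_expectation"} (piecewise-linear through points of the
#'   expectation curve at increments of \code{step}),
#'   \code{"continuous_expectation"} (the expectation curve itself,
#'   integrated in closed form), or \code{"ap"} (step curve; rectangle of
#'   height equal to the right anchor's precision).
#' @param step positive increment for \code{"discrete_expectation"};
#'   1 interpolates one point per additional true positive, 0.5 doubles the
#'   density. With \code{step >= dtp} the segment degenerates to a single
#'   chord whose endpoints lie on the expectation curve.
#' @param pFrom precision at the left end of the segment. Defaults to the
#'   left anchor's precision; must be supplied (or is derived per method)
#'   when the group starts at the virtual origin. Pass 1 to reproduce the
#'   fabricated (0, 1) start convention.
#' @param n sampling density for the continuous curve's \code{points}.
#'
#' @return A list with elements \code{points} (matrix of (recall,
#'   precision) vertices realized on the curve), \code{area}, \code{method}
#'   and \code{group}.
#'
#' @examples
#' ## an all-tied classifier traversed by each method
#' g <- tieGroup(0, 0, dtp = 32, dfp = 42, nPos = 32)
#' connectSegment(g, "continuous_expectation")$area  # prevalence: 32/74
#' connectSegment(g, "linear", pFrom = 1)$area       # optimistic chord
#' @export
connectSegment <- function(group, method = .METHODS, step = 1,
                           pFrom = NULL, n = 64) {
  stopifnot(is(group, "TieGroup"))
  method <- match.arg(method)
  if (method == "discrete_expectation" && step <= 0)
    stop("step must be positive")
  tpA <- group@tpFrom; fpA <- group@fpFrom
  dtp <- group@dtp; dfp <- group@dfp
  P <- group@nPos
  if (is.null(pFrom))
    pFrom <- if (tpA + fpA > 0L) tpA / (tpA + fpA) else NA_real_
  fromOrigin <- (tpA + fpA == 0L)
  ## a supplied start overrides the derived one only where the segment's
  ## own geometry starts elsewhere (linear chord; plotted step drop)
  areaPFrom <- pFrom
  if (fromOrigin && !is.na(pFrom) &&
      method %in% c("discrete_expectation", "continuous_expectation")) {
    ## expectation from the origin is constant; a fabricated (0,1) start is
    ## emulated as a straight chord to the first anchor (see buildPRCurve)
    areaPFrom <- NA_real_
  }
  area <- .segmentArea(method, tpA, fpA, dtp, dfp, P, step, areaPFrom)
  points <- .segmentPoints(method, tpA, fpA, dtp, dfp, P, step, pFrom, n)
  list(points = points, area = area, method = method, group = group)
}
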