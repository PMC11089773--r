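#' @import methods
NULL

#' Scored, labeled entities
#'
#' Container for the output of a binary classifier: one real-valued
#' classification score and one binary ground-truth label per entity.
#' Row order is preserved because some emulation profiles (see
#' \code{\link{profileCatalogue}}) are deliberately sensitive to the input
#' order of tied entities.
#'
#' @slot scores numeric vector of finite classification scores; ties allowed.
#' @slot labels integer vector of the same length, 1 = actual positive,
#'   0 = actual negative.
#' @slot ids character vector of entity identifiers (may be empty).
#'
#' @seealso \code{\link{ScoredLabels}} for the user-facing constructor.
#' @export
setClass("ScoredLabels",
  representation(scores = "numeric", labels = "integer", ids = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@scores) != length(object@labels))
      msg <- c(msg, "scores and labels must have equal length")
    if (length(object@scores) < 1L)
      msg <- c(msg, "at least one entity is required")
    if (any(!is.finite(object@scores)))
      msg <- c(msg, "non-finite score")
    if (any(!object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 or 1")
    if (length(object@ids) > 0L &&
        length(object@ids) != length(object@scores))
      msg <- c(msg, "ids must be empty or match the number of entities")
    if (is.null(msg)) TRUE else msg
  }
)

#' A tie group: the increment between two adjacent anchor points
#'
#' All entities sharing one classification score form a tie group that
#' contributes \code{dtp} true positives and \code{dfp} false positives
#' between the flanking anchor points. \code{tpFrom = fpFrom = 0} marks a
#' group that starts at the virtual origin (recall 0, precision undefined),
#' which is a distinguished sentinel and never an anchor point itself.
#'
#' @slot tpFrom,fpFrom cumulative true/false positive counts at the
#'   higher-score flanking anchor (0, 0 for the virtual origin).
#' @slot dtp,dfp non-negative counts of positives/negatives in the group;
#'   \code{dtp + dfp >= 1}.
#' @slot nPos total number of actual positives in the data set (the recall
#'   denominator).
#'
#' @seealso \code{\link{tieGroup}}, \code{\link{computeAnchorPoints}}
#' @export
setClass("TieGroup",
  representation(tpFrom = "integer", fpFrom = "integer",
                 dtp = "integer", dfp = "integer", nPos = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@dtp < 0L || object@dfp < 0L)
      msg <- c(msg, "dtp and dfp must be non-negative")
    if (object@dtp + object@dfp < 1L)
      msg <- c(msg, "a tie group must contain at least one entity")
    if (object@tpFrom < 0L || object@fpFrom < 0L)
      msg <- c(msg, "tpFrom and fpFrom must be non-negative")
    if (object@nPos < 1L)
      msg <- c(msg, "nPos must be at least 1")
    if (object@tpFrom + object@dtp > object@nPos)
      msg <- c(msg, "tpFrom + dtp exceeds nPos")
    if (is.null(msg)) TRUE else msg
  }
)

#' A precision-recall curve with an explicit connection method
#'
#' Holds the anchor points of a PR curve together with the per-tie-group
#' segments produced by one of the four connection methods, the start
#' convention used to extend the curve to recall zero, and the resulting
#' AUPRC (the sum of the exact segment areas).
#'
#' @slot anchors data.frame with columns \code{threshold}, \code{tp},
#'   \code{fp}, \code{recall}, \code{precision}, one row per unique score in
#'   descending score order.
#' @slot segments data.frame with one row per tie group (the first row is
#'   the origin segment unless coverage is truncated): columns
#'   \code{method}, \code{tpFrom}, \code{fpFrom}, \code{dtp}, \code{dfp},
#'   \code{rFrom}, \code{rTo}, \code{pFrom}, \code{pTo}, \code{area}.
#' @slot method character; connection method requested (or a profile name
#'   for mixed-method curves).
#' @slot step numeric; interpolation increment of the discrete expectation
#'   method.
#' @slot startConvention \code{"derived"} or \code{"fixed01"}.
#' @slot auprc numeric; sum of segment areas.
#' @slot nPos,nNeg integer class counts.
#'
#' @seealso \code{\link{buildPRCurve}}, \code{\link{auprc}},
#'   \code{\link{curvePoints}}
#' @export
setClass("PRCurve",
  representation(anchors = "data.frame", segments = "data.frame",
                 method = "character", step = "numeric",
                 startConvention = "character", auprc = "numeric",
                 nPos = "integer", nNeg = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@startConvention %in% c("derived", "fixed01", "none"))
      msg <- c(msg, "unknown start convention")
    if (length(object@auprc) != 1L || is.na(object@auprc) ||
        object@auprc < 0 || object@auprc > 1 + 1e-12)
      msg <- c(msg, "auprc must be a single value in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' An emulation profile: one surveyed tool's documented behavior
#'
#' A named bundle of connection methods and convention flags reproducing the
#' documented behavior of one widely used PRC/AUPRC implementation: which
#' method connects anchors when scores are distinct, which handles tie
#' groups, whether the curve start is fabricated at (0, 1), whether the
#' curve covers the full recall range, whether tied entities are sequenced
#' by their input order, and whether anchor points are dropped from the
#' exported curve. Profiles emulate documented method combinations and
#' conventions, not third-party source code.
#'
#' @slot name tool identifier.
#' @slot noTieMethod,tieMethod one of \code{"linear"},
#'   \code{"discrete_expectation"}, \code{"continuous_expectation"},
#'   \code{"ap"}, applied to size-1 and size->1 tie groups respectively.
#' @slot startConvention \code{"derived"} (extend with the method's own
#'   limit) or \code{"fixed01"} (force the start point (0, 1)).
#' @slot fullCoverage logical; \code{FALSE} marks tools whose curve is not
#'   guaranteed to span recall 0 to 1: the upper integration bound stops at
#'   the last anchor derived from observed scores instead of forcing a
#'   recall-1 terminal (numerically inert under the inclusive threshold
#'   rule, where that anchor already has recall 1).
#' @slot tieOrderSensitive logical; \code{TRUE} sequences tied entities by
#'   input order and treats them as if their scores were distinct.
#' @slot dropAnchors logical; \code{TRUE} omits each segment's left anchor
#'   from exported curve points (a visualization defect; AUPRC unaffected).
#' @slot step numeric; discrete-expectation increment.
#'
#' @seealso \code{\link{methodProfile}}, \code{\link{profileCatalogue}},
#'   \code{\link{evaluateWithProfile}}
#' @export
setClass("MethodProfile",
  representation(name = "character", noTieMethod = "character",
                 tieMethod = "character", startConvention = "character",
                 fullCoverage = "logical", tieOrderSensitive = "logical",
                 dropAnchors = "logical", step = "numeric"),
  validity = function(object) {
    methods <- c("linear", "discrete_expectation",
                 "continuous_expectation", "ap")
    msg <- NULL
    if (!object@noTieMethod %in% methods)
      msg <- c(msg, "unknown noTieMethod")
    if (!object@tieMethod %in% methods)
      msg <- c(msg, "unknown tieMethod")
    if (!object@startConvention %in% c("derived", "fixed01"))
      msg <- c(msg, "unknown start convention")
    if (object@step <= 0)
      msg <- c(msg, "step must be positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' Evaluation report for one data set under one profile
#'
#' Bundles the AUPRC obtained under an emulation profile with the
#' quantities needed to interpret it: the trapezoidal AUROC (on which the
#' surveyed tools largely agree), the prevalence baseline P/(P+N) that a
#' no-skill classifier attains, and the list of known conceptual issues the
#' selected profile embodies. Every report also records the methods and
#' conventions used, so that results can be cited unambiguously.
#'
#' @slot profile profile name.
#' @slot noTieMethod,tieMethod,startConvention,step the configuration used.
#' @slot auprc,auroc,baseline numeric results.
#' @slot issues character vector of issue tags embodied by the profile.
#' @slot nPos,nNeg,nAnchors integer problem dimensions.
#' @slot version package version string.
#'
#' @seealso \code{\link{evaluateWithProfile}}, \code{\link{writeReport}}
#' @export
setClass("EvaluationReport",
  representation(profile = "character", noTieMethod = "character",
                 tieMethod = "character", startConvention = "character",
                 step = "numeric", auprc = "numeric", auroc = "numeric",
                 baseline = "numeric", issues = "character",
                 nPos = "integer", nNeg = "integer", nAnchors = "integer",
                 version = "character"))

#' AUPRC and rank matrices for a set of submissions
#'
#' The cross-profile disagreement summary: AUPRC of every submission under
#' every profile, and the per-profile ranking (1 = best; tied values share
#' the better rank).
#'
#' @slot values numeric matrix, submissions x profiles.
#' @slot ranks integer matrix of the same shape.
#'
#' @seealso \code{\link{scoreAll}}, \code{\link{rankFlips}},
#'   \code{\link{profileCorrelations}}
#' @export
setClass("RankMatrix",
  representation(values = "matrix", ranks = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), dim(object@ranks)))
      msg <- c(msg, "values and ranks must have identical dimensions")
    for (j in seq_len(ncol(object@values))) {
      expect <- rank(-object@values[, j], ties.method = "min")
      if (!isTRUE(all.equal(as.vector(object@ranks[, j]), as.vector(expect))))
        msg <- c(msg, sprintf("column %d ranks do not match its values", j))
    }
    if (is.null(msg)) TRUE else msg
  }
)
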