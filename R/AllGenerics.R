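#' @rdname computeAnchorPoints
#' @export
setGeneric("computeAnchorPoints",
           function(data) standardGeneric("computeAnchorPoints"))

#' @rdname confusionAtThreshold
#' @export
setGeneric("confusionAtThreshold",
           function(data, t) standardGeneric("confusionAtThreshold"))

#' @rdname buildPRCurve
#' @export
setGeneric("buildPRCurve",
           function(data, method = "continuous_expectation", step = 1,
                    startConvention = "derived")
             standardGeneric("buildPRCurve"))

#' @rdname auprc
#' @export
setGeneric("auprc", function(x, ...) standardGeneric("auprc"))

#' @rdname auroc
#' @export
setGeneric("auroc", function(data) standardGeneric("auroc"))

#' @rdname evaluateWithProfile
#' @export
setGeneric("evaluateWithProfile",
           function(data, profile) standardGeneric("evaluateWithProfile"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("nPos", function(x) standardGeneric("nPos"))

#' @rdname accessors
#' @export
setGeneric("nNeg", function(x) standardGeneric("nNeg"))

#' @rdname accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname curve-accessors
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))

#' @rdname curve-accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname curvePoints
#' @export
setGeneric("curvePoints",
           function(x, pointsPerSegment = 64, dropAnchors = FALSE)
             standardGeneric("curvePoints"))

#' @rdname rankmatrix-accessors
#' @export
setGeneric("auprcValues", function(x) standardGeneric("auprcValues"))

#' @rdname rankmatrix-accessors
#' @export
setGeneric("rankValues", function(x) standardGeneric("rankValues"))

#' @rdname profileIssues
#' @export
setGeneric("profileIssues", function(x) standardGeneric("profileIssues"))
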