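#' Construct an emulation profile
#'
#' @param name profile / tool identifier.
#' @param noTieMethod method connecting adjacent anchors of size-1 groups.
#' @param tieMethod method connecting across tie groups of size > 1.
#' @param startConvention \code{"derived"} or \code{"fixed01"}.
#' @param fullCoverage if \code{FALSE}, the curve is not guaranteed to span
#'   the full recall range: integration stops at the last anchor derived
#'   from observed scores rather than forcing a recall-1 terminal. Under
#'   this package's inclusive threshold rule that anchor already has
#'   recall 1, so the flag changes no areas; it records the documented
#'   convention and is reported as an issue.
#' @param tieOrderSensitive if \code{TRUE}, tied entities are sequenced by
#'   their input order and anchors computed as if all scores were distinct,
#'   making the result input-order dependent by design.
#' @param dropAnchors if \code{TRUE}, exported curve points retain only
#'   each segment's right anchor (affects visualization, never AUPRC).
#' @param step discrete-expectation increment.
#' @return A \code{\linkS4class{MethodProfile}} object.
#' @seealso \code{\link{profileCatalogue}} for the shipped catalogue,
#'   \code{\link{referenceProfile}} for the recommended configuration.
#' @export
methodProfile <- function(name, noTieMethod, tieMethod,
                          startConvention = "derived", fullCoverage = TRUE,
                          tieOrderSensitive = FALSE, dropAnchors = FALSE,
                          step = 1) {
  new("MethodProfile", name = name,
      noTieMethod = match.arg(noTieMethod, .METHODS),
      tieMethod = match.arg(tieMethod, .METHODS),
      startConvention = match.arg(startConvention, c("derived", "fixed01")),
      fullCoverage = fullCoverage, tieOrderSensitive = tieOrderSensitive,
      dropAnchors = dropAnchors, step = step)
}

#' Known conceptual issues a profile embodies
#'
#' Maps a profile's configuration to the five documented defect classes:
#' \describe{
#'   \item{linear_ties}{linear interpolation across tie groups, which can
#'     produce overly-optimistic AUPRC values.}
#'   \item{fixed_start}{always using (0, 1) as the curve's starting point,
#'     inconsistent with the AP and expectation methods whenever the first
#'     anchor's precision is below one.}
#'   \item{incomplete_coverage}{the curve does not cover the full recall
#'     range from 0 to 1.}
#'   \item{order_dependent_ties}{tied entities are sequenced by input order
#'     and handled as if their scores were distinct.}
#'   \item{dropped_anchors}{not all anchor points are placed on the
#'     exported curve.}
#' }
#'
#' @param x a \code{\linkS4class{MethodProfile}}.
#' @return character vector of issue tags (empty for a clean profile).
#' @export
setMethod("profileIssues", "MethodProfile", function(x) {
  issues <- character(0)
  # order-sensitive profiles never apply a tie-group method, so linear tie
  # interpolation is not among their defects
  if (x@tieMethod == "linear" && !x@tieOrderSensitive)
    issues <- c(issues, "linear_ties")
  if (x@startConvention == "fixed01") issues <- c(issues, "fixed_start")
  if (!x@fullCoverage) issues <- c(issues, "incomplete_coverage")
  if (x@tieOrderSensitive) issues <- c(issues, "order_dependent_ties")
  if (x@dropAnchors) issues <- c(issues, "dropped_anchors")
  issues
})

setMethod("show", "MethodProfile", function(object) {
  iss <- profileIssues(object)
  cat(sprintf("MethodProfile '%s': no-tie = %s, tie = %s, start = %s\n",
              object@name, object@noTieMethod, object@tieMethod,
              object@startConvention))
  cat(sprintf("  issues: %s\n",
              if (length(iss)) paste(iss, collapse = ", ") else "none"))
})

#' The reference profile
#'
#' Order-independent tie handling, a start point derived from the method's
#' own limit at recall 0, full recall coverage, and all anchors retained.
#'
#' @param method connection method used for both regimes (default
#'   continuous expectation, whose all-tied AUPRC equals prevalence
#'   exactly).
#' @param step discrete-expectation increment.
#' @return A \code{\linkS4class{MethodProfile}}.
#' @export
referenceProfile <- function(method = "continuous_expectation", step = 1) {
  method <- match.arg(method, .METHODS)
  methodProfile("reference", method, method, step = step)
}

#' Catalogue of surveyed-tool emulation profiles
#'
#' One profile per documented method combination of the widely used
#' PRC/AUPRC implementations (tools offering several methods contribute
#' one profile each): ROCR, Weka, scikit-learn (linear and AP variants),
#' PerfMeas, PRROC (discrete and continuous expectation variants),
#' TensorFlow, precrec, TorchEval, MLeval, and yardstick (linear and AP
#' variants). Each profile captures the tool's documented anchor-connection
#' methods plus its convention flags (fabricated (0, 1) start, incomplete
#' recall coverage, input-order-dependent ties, dropped anchor points).
#' Emulation targets documented behavior, not bit-exact replication of
#' third-party source code.
#'
#' @param names optional character vector to subset the catalogue.
#' @return Named list of \code{\linkS4class{MethodProfile}} objects,
#'   including the \code{"reference"} profile.
#' @examples
#' sapply(profileCatalogue(), profileIssues)
#' @export
profileCatalogue <- function(names = NULL) {
  cat <- list(
    reference = referenceProfile(),
    ROCR = methodProfile("ROCR", "linear", "discrete_expectation",
                         startConvention = "fixed01", dropAnchors = TRUE),
    Weka = methodProfile("Weka", "ap", "ap"),
    `scikit-learn (linear)` = methodProfile("scikit-learn (linear)",
                         "linear", "linear", startConvention = "fixed01"),
    `scikit-learn (AP)` = methodProfile("scikit-learn (AP)", "ap", "ap"),
    PerfMeas = methodProfile("PerfMeas", "linear", "linear",
                         fullCoverage = FALSE, tieOrderSensitive = TRUE),
    `PRROC (discrete)` = methodProfile("PRROC (discrete)", "linear",
                         "discrete_expectation"),
    `PRROC (continuous)` = methodProfile("PRROC (continuous)",
                         "continuous_expectation", "continuous_expectation"),
    TensorFlow = methodProfile("TensorFlow", "continuous_expectation",
                         "continuous_expectation"),
    precrec = methodProfile("precrec", "discrete_expectation",
                         "discrete_expectation"),
    TorchEval = methodProfile("TorchEval", "ap", "ap"),
    MLeval = methodProfile("MLeval", "linear", "linear",
                         fullCoverage = FALSE),
    `yardstick (linear)` = methodProfile("yardstick (linear)", "linear",
                         "linear", startConvention = "fixed01"),
    `yardstick (AP)` = methodProfile("yardstick (AP)", "ap", "ap")
  )
  if (is.null(names)) return(cat)
  missing <- setdiff(names, base::names(cat))
  if (length(missing))
    stop("unknown profile name(s): ", paste(missing, collapse = ", "))
  cat[names]
}

## Build the PRCurve a profile produces on one data set. Input row order is
## significant only for tie-order-sensitive profiles, which sequence tied
## entities by their position and treat every entity as its own anchor.
.profileCurve <- function(data, profile) {
  P <- nPos(data); N <- nNeg(data)
  if (P == 0L) stop("no positive entities")
  if (profile@tieOrderSensitive) {
    ord <- order(data@scores, decreasing = TRUE, method = "radix")  # stable
    l <- data@labels[ord]
    tp <- cumsum(l)
    fp <- seq_along(l) - tp
    anchors <- data.frame(threshold = data@scores[ord], tp = tp, fp = fp,
                          recall = tp / P, precision = tp / (tp + fp))
    groups <- data.frame(tpFrom = c(0L, tp[-length(tp)]),
                         fpFrom = c(0L, fp[-length(fp)]),
                         dtp = as.integer(l), dfp = 1L - as.integer(l))
    methods <- rep(profile@noTieMethod, nrow(groups))
  } else {
    ap <- computeAnchorPoints(data)
    anchors <- ap$anchors
    groups <- ap$groups
    methods <- ifelse(groups$dtp + groups$dfp > 1L,
                      profile@tieMethod, profile@noTieMethod)
  }
  .buildCurve(anchors, groups, P, N, methods, profile@step,
              profile@startConvention, profile@fullCoverage,
              label = profile@name)
}

#' Evaluate a data set under an emulation profile
#'
#' Applies the profile's method pair and convention flags and reports the
#' resulting AUPRC next to the reference AUROC, the prevalence baseline,
#' and the list of known conceptual issues the profile embodies.
#'
#' @param data a \code{\linkS4class{ScoredLabels}} object.
#' @param profile a \code{\linkS4class{MethodProfile}} or the name of a
#'   catalogue profile.
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @examples
#' sl <- ScoredLabels(c(.9, .8, .7, .6), c(1, 1, 0, 1))
#' evaluateWithProfile(sl, "reference")
#' @export
setMethod("evaluateWithProfile",
          signature(data = "ScoredLabels", profile = "MethodProfile"),
  function(data, profile) {
    curve <- .profileCurve(data, profile)
    new("EvaluationReport", profile = profile@name,
        noTieMethod = profile@noTieMethod, tieMethod = profile@tieMethod,
        startConvention = profile@startConvention, step = profile@step,
        auprc = curve@auprc,
        auroc = if (nNeg(data) > 0L) auroc(data) else NA_real_,
        baseline = prevalence(data), issues = profileIssues(profile),
        nPos = nPos(data), nNeg = nNeg(data),
        nAnchors = nrow(curve@anchors),
        version = as.character(utils::packageVersion("prcties")))
  })

#' @rdname evaluateWithProfile
#' @export
setMethod("evaluateWithProfile",
          signature(data = "ScoredLabels", profile = "character"),
  function(data, profile) {
    evaluateWithProfile(data, profileCatalogue(profile)[[1]])
  })

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s]\n", object@profile))
  cat(sprintf("  AUPRC   = %.3f   (baseline %.3f)\n", object@auprc,
              object@baseline))
  cat(sprintf("  AUROC   = %.3f\n", object@auroc))
  cat(sprintf("  methods: no-tie = %s, tie = %s, start = %s, step = %g\n",
              object@noTieMethod, object@tieMethod, object@startConvention,
              object@step))
  cat(sprintf("  issues : %s\n",
              if (length(object@issues))
                paste(object@issues, collapse = ", ") else "none"))
})
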