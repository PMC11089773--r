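#' Simulate classifier scores with controlled tie structure
#'
#' Generates score/label data sets spanning the regimes that stress AUPRC
#' estimation differently:
#' \describe{
#'   \item{gaussian2}{continuous scorer: negatives drawn from a standard
#'     normal, positives from a normal shifted by \code{separation}; ties
#'     are almost surely absent.}
#'   \item{discretized}{the gaussian2 scores quantized onto
#'     \code{nLevels} equal-width bins (the bin index is the score),
#'     guaranteeing large tie groups whenever \code{nLevels} is smaller
#'     than the number of entities — the regime of coarse scorers such as
#'     small random forests.}
#'   \item{cluster_binary}{a single-group binary predictor: a chosen
#'     cluster of cells is predicted positive (score 1) and everything else
#'     negative (score 0), giving exactly two tie groups — the structure of
#'     a cell-type assignment treated as a classifier.}
#'   \item{random}{scores uniform on (0, 1), independent of the labels; a
#'     no-skill classifier whose expected continuous-expectation AUPRC is
#'     the prevalence P/(P+N).}
#' }
#'
#' @param nPos,nNeg class counts (positives >= 1).
#' @param model one of \code{"gaussian2"}, \code{"discretized"},
#'   \code{"cluster_binary"}, \code{"random"}.
#' @param separation location shift of the positive score distribution
#'   (gaussian2/discretized), in standard deviations.
#' @param nLevels number of quantization levels (discretized).
#' @param nPredicted size of the predicted-positive cluster
#'   (cluster_binary); defaults to one tenth of the entities.
#' @param tpInPredicted actual positives inside the predicted cluster
#'   (cluster_binary); defaults to 70\% of the cluster, capped at
#'   \code{nPos}.
#' @param seed optional integer; the same seed yields identical output.
#' @return A \code{\linkS4class{ScoredLabels}} object.
#' @examples
#' sl <- simulateScores(20, 80, "discretized", nLevels = 5, seed = 1)
#' nrow(computeAnchorPoints(sl)$anchors) <= 5
#' @export
simulateScores <- function(nPos, nNeg,
                           model = c("gaussian2", "discretized",
                                     "cluster_binary", "random"),
                           separation = 1, nLevels = 10,
                           nPredicted = NULL, tpInPredicted = NULL,
                           seed = NULL) {
  model <- match.arg(model)
  if (nPos < 1L) stop("nPos must be at least 1")
  if (nNeg < 0L) stop("nNeg must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nPos + nNeg
  labels <- rep(c(1L, 0L), c(nPos, nNeg))
  scores <- switch(model,
    gaussian2 = c(stats::rnorm(nPos, mean = separation), stats::rnorm(nNeg)),
    discretized = {
      if (nLevels < 1L) stop("nLevels must be at least 1")
      raw <- c(stats::rnorm(nPos, mean = separation), stats::rnorm(nNeg))
      if (nLevels == 1L) rep(1, n)
      else {
        br <- seq(min(raw), max(raw), length.out = nLevels + 1L)
        idx <- findInterval(raw, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
        as.numeric(idx)
      }
    },
    cluster_binary = {
      if (is.null(nPredicted)) nPredicted <- max(1L, round(n / 10))
      if (is.null(tpInPredicted))
        tpInPredicted <- min(nPos, nPredicted, round(0.7 * nPredicted))
      if (tpInPredicted > min(nPos, nPredicted))
        stop("tpInPredicted exceeds nPos or nPredicted")
      if (nPredicted - tpInPredicted > nNeg)
        stop("predicted cluster needs more negatives than available")
      s <- numeric(n)
      s[seq_len(tpInPredicted)] <- 1                      # positives in cluster
      s[nPos + seq_len(nPredicted - tpInPredicted)] <- 1  # negatives in cluster
      s
    },
    random = stats::runif(n)
  )
  ScoredLabels(scores, labels, ids = sprintf("e%d", seq_len(n)))
}

#' Deterministic fixture data sets
#'
#' Small canned score/label sets covering the degenerate configurations
#' the connection methods disagree on. The tied fixtures reproduce tie
#' STRUCTURE (group sizes and class composition), not any external data
#' set's actual score values.
#'
#' \describe{
#'   \item{no_ties_small}{10 entities, all scores distinct (4 positives).}
#'   \item{four_tie_groups}{13 entities in 4 score groups of sizes 3, 7, 2
#'     and 1, so exactly 4 anchor points.}
#'   \item{all_tied}{74 entities sharing one score: 32 positives, 42
#'     negatives; a single-anchor curve whose continuous-expectation AUPRC
#'     is the prevalence 32/74.}
#'   \item{all_tied_balanced}{8 positives and 8 negatives on one score;
#'     the balanced case where the fabricated-(0,1) linear area is 0.75
#'     against 0.5 for the expectation and AP methods.}
#'   \item{perfect}{5 positives all scored above 5 negatives, no ties;
#'     AUPRC 1 under every method.}
#'   \item{one_pos_last}{a single positive carrying the lowest score.}
#' }
#'
#' @param name fixture name.
#' @return A \code{\linkS4class{ScoredLabels}} object.
#' @examples
#' nrow(computeAnchorPoints(prcFixture("four_tie_groups"))$anchors)  # 4
#' @export
prcFixture <- function(name = c("no_ties_small", "four_tie_groups",
                                "all_tied", "all_tied_balanced", "perfect",
                                "one_pos_last")) {
  name <- match.arg(name)
  switch(name,
    no_ties_small = ScoredLabels(
      seq(0.95, 0.05, by = -0.1),
      c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)),
    four_tie_groups = ScoredLabels(
      rep(c(0.9, 0.7, 0.5, 0.3), c(3L, 7L, 2L, 1L)),
      c(1L, 1L, 0L,                       # group of 3: 2 pos
        1L, 1L, 1L, 0L, 0L, 0L, 0L,      # group of 7: 3 pos
        1L, 0L,                           # group of 2: 1 pos
        1L)),                             # group of 1: 1 pos
    all_tied = ScoredLabels(rep(0.5, 74), rep(c(1L, 0L), c(32L, 42L))),
    all_tied_balanced = ScoredLabels(rep(0.5, 16), rep(c(1L, 0L), each = 8L)),
    perfect = ScoredLabels(seq(1, 0.1, by = -0.1),
                           rep(c(1L, 0L), each = 5L)),
    one_pos_last = ScoredLabels(seq(0.9, 0.1, by = -0.1),
                                c(rep(0L, 8L), 1L))
  )
}
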