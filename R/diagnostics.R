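## Cross-profile disagreement diagnostics: AUPRC matrices, per-profile
## rankings, rank flips, and correlation summaries for a set of classifier
## submissions evaluated against one shared ground truth.

.checkSubmissionSet <- function(submissions) {
  if (!is.list(submissions) || length(submissions) < 1L)
    stop("submissions must be a non-empty list of ScoredLabels")
  if (!all(vapply(submissions, is, logical(1), "ScoredLabels")))
    stop("submissions must be a non-empty list of ScoredLabels")
  ref <- trueLabels(submissions[[1]])
  for (i in seq_along(submissions)) {
    if (!identical(trueLabels(submissions[[i]]), ref))
      stop("submission ", i, " has a mismatched label vector")
  }
  if (is.null(names(submissions)))
    names(submissions) <- paste0("submission", seq_along(submissions))
  submissions
}

#' AUPRC of every submission under every profile
#'
#' Evaluates a set of classifier submissions (scores over the same entities
#' and shared ground-truth labels) under each emulation profile and ranks
#' them per profile, 1 = best, tied AUPRC values sharing the better
#' (minimum) rank.
#'
#' @param submissions named list of \code{\linkS4class{ScoredLabels}} with
#'   identical label vectors; at least 2.
#' @param profiles list of \code{\linkS4class{MethodProfile}} objects or a
#'   character vector of catalogue names; at least 2. Defaults to the full
#'   shipped catalogue.
#' @return A \code{\linkS4class{RankMatrix}}.
#' @examples
#' labs <- rep(c(1, 0), c(3, 7))
#' subs <- list(a = ScoredLabels(10:1 / 10, labs),
#'              b = ScoredLabels(rep(0.5, 10), labs))
#' scoreAll(subs, c("scikit-learn (linear)", "Weka"))
#' @export
scoreAll <- function(submissions, profiles = profileCatalogue()) {
  submissions <- .checkSubmissionSet(submissions)
  if (is.character(profiles)) profiles <- profileCatalogue(profiles)
  if (length(submissions) < 2L) stop("at least 2 submissions are required")
  if (length(profiles) < 2L) stop("at least 2 profiles are required")
  pNames <- vapply(profiles, function(p) p@name, character(1))
  values <- matrix(NA_real_, length(submissions), length(profiles),
                   dimnames = list(names(submissions), pNames))
  for (j in seq_along(profiles))
    for (i in seq_along(submissions))
      values[i, j] <- .profileCurve(submissions[[i]], profiles[[j]])@auprc
  ranks <- apply(values, 2, function(v) rank(-v, ties.method = "min"))
  dimnames(ranks) <- dimnames(values)
  new("RankMatrix", values = values, ranks = ranks)
}

#' @rdname rankmatrix-accessors
#' @export
setMethod("auprcValues", "RankMatrix", function(x) x@values)

#' Accessors for RankMatrix
#'
#' @param x a \code{\linkS4class{RankMatrix}}.
#' @return \code{auprcValues}: the submissions x profiles AUPRC matrix;
#'   \code{rankValues}: the per-profile ranking matrix.
#' @name rankmatrix-accessors
#' @aliases auprcValues rankValues
#' @export
setMethod("rankValues", "RankMatrix", function(x) x@ranks)

setMethod("show", "RankMatrix", function(object) {
  cat(sprintf("RankMatrix: %d submissions x %d profiles\n",
              nrow(object@values), ncol(object@values)))
  print(round(object@values, 3))
})

#' Rank flips between profiles
#'
#' Enumerates every pair of submissions and every pair of profiles for
#' which the relative AUPRC order strictly reverses: a pair counts as a
#' flip when one submission's AUPRC is strictly higher under one profile
#' and strictly lower under the other. An empty result means all profile
#' columns induce compatible orderings.
#'
#' @param x a \code{\linkS4class{RankMatrix}}.
#' @return data.frame with columns \code{submission1}, \code{submission2},
#'   \code{profile1}, \code{profile2} (one row per flip; zero rows when
#'   there are none).
#' @export
rankFlips <- function(x) {
  stopifnot(is(x, "RankMatrix"))
  v <- x@values
  subs <- rownames(v); profs <- colnames(v)
  out <- list()
  for (i in seq_len(nrow(v) - 1L)) for (j in seq(i + 1L, nrow(v))) {
    d <- v[i, ] - v[j, ]
    for (a in seq_len(ncol(v) - 1L)) for (b in seq(a + 1L, ncol(v))) {
      if (d[a] * d[b] < 0)
        out[[length(out) + 1L]] <- data.frame(
          submission1 = subs[i], submission2 = subs[j],
          profile1 = profs[a], profile2 = profs[b])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(submission1 = character(0), submission2 = character(0),
                  profile1 = character(0), profile2 = character(0))
}

#' Between-profile correlation of AUPRC values and ranks
#'
#' Pearson correlation of the raw AUPRC columns and Spearman correlation
#' (rank-based) between every pair of profiles. A profile column with zero
#' variance has no defined correlation and is reported as \code{NA}, never
#' as 0.
#'
#' @param x a \code{\linkS4class{RankMatrix}} with at least 3 submissions.
#' @return list with symmetric matrices \code{pearson} and
#'   \code{spearman}, unit diagonal.
#' @export
profileCorrelations <- function(x) {
  stopifnot(is(x, "RankMatrix"))
  if (nrow(x@values) < 3L) stop("at least 3 submissions are required")
  pe <- suppressWarnings(stats::cor(x@values, method = "pearson"))
  sp <- suppressWarnings(stats::cor(x@values, method = "spearman"))
  diag(pe) <- 1; diag(sp) <- 1
  list(pearson = pe, spearman = sp)
}
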