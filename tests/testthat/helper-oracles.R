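## Independent oracles used across the suite. These deliberately avoid the
## package's own closed forms: areas come from adaptive quadrature, AUROC
## from brute-force pair counting.

## Exact-by-quadrature area of the continuous expectation segment of a
## tie group, in recall space.
quadratureArea <- function(group) {
  if (group@dtp == 0L) return(0)
  stats::integrate(function(x) expectationPrecision(group, x),
                   lower = 0, upper = group@dtp,
                   rel.tol = 1e-13, abs.tol = 1e-13)$value / group@nPos
}

## Mann-Whitney AUROC by O(P*N) pair enumeration with half credit for ties.
pairCountAUROC <- function(sl) {
  s <- scoreValues(sl); l <- trueLabels(sl)
  pos <- s[l == 1L]; neg <- s[l == 0L]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## Trapezoidal integration of densely sampled curve points.
trapzPoints <- function(pts) {
  r <- pts$recall; p <- pts$precision
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

## Random tie group with a valid flanking-anchor context.
randomTieGroup <- function() {
  tpA <- sample(0:15, 1)
  fpA <- if (tpA == 0L) sample(1:15, 1) else sample(0:15, 1)
  dtp <- sample(1:10, 1)
  dfp <- sample(0:10, 1)
  tieGroup(tpA, fpA, dtp, dfp, nPos = tpA + dtp + sample(0:5, 1))
}

## Random small ScoredLabels instance with a tunable tie regime.
randomInstance <- function(n = 20, tied = TRUE) {
  labels <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))  # both classes
  scores <- if (tied) sample(seq(0.1, 0.5, by = 0.1), n, replace = TRUE)
            else sample(seq_len(n * 10), n) / (n * 10)
  ScoredLabels(scores, labels)
}

ALL_METHODS <- c("linear", "discrete_expectation", "continuous_expectation",
                 "ap")
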