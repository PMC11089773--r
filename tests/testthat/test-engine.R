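test_that("a perfectly separating classifier scores AUPRC 1 under every
           method and profile", {
  sl <- prcFixture("perfect")
  for (m in ALL_METHODS)
    expect_equal(auprc(sl, method = m), 1)
  for (p in profileCatalogue())
    expect_equal(evaluateWithProfile(sl, p)@auprc, 1)
})

test_that("an all-tied classifier's continuous-expectation AUPRC is the
           prevalence baseline", {
  # 32 positives / 42 negatives -> 0.432 at 3 d.p.
  curve <- buildPRCurve(prcFixture("all_tied"), "continuous_expectation")
  expect_equal(auprc(curve), 32 / 74)
  expect_equal(round(auprc(curve), 3), 0.432)
  # 4012 positives / 274,380 negatives -> 0.014 at 3 d.p.
  big <- ScoredLabels(rep(0, 4012 + 274380),
                      rep(c(1L, 0L), c(4012L, 274380L)))
  expect_equal(round(auprc(big, method = "continuous_expectation"), 3),
               0.014)
  # the identity holds for arbitrary class sizes
  set.seed(3)
  for (i in 1:20) {
    P <- sample(1:200, 1); N <- sample(1:200, 1)
    sl <- ScoredLabels(rep(1, P + N), rep(c(1L, 0L), c(P, N)))
    expect_equal(auprc(sl, method = "continuous_expectation"), P / (P + N))
  }
})

test_that("the start convention changes the area iff the first anchor's
           precision is below one", {
  # first anchor precision 1: conventions agree
  sl1 <- ScoredLabels(c(0.9, 0.1), c(1, 0))
  expect_equal(auprc(sl1, method = "linear", startConvention = "fixed01"),
               auprc(sl1, method = "linear", startConvention = "derived"))
  # first anchor precision 1/2: fixed01 adds the start triangle
  sl2 <- ScoredLabels(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 1, 0))
  ap1 <- computeAnchorPoints(sl2)$anchors[1, ]
  expect_lt(ap1$precision, 1)
  fixed <- auprc(sl2, method = "linear", startConvention = "fixed01")
  derived <- auprc(sl2, method = "linear", startConvention = "derived")
  # analytic areas of the two start triangles on this instance:
  # derived starts at (0, 1/2), fixed01 at (0, 1)
  expect_equal(fixed - derived, ap1$recall * (1 + 1 / 2) / 2 -
                 ap1$recall * 1 / 2)
  expect_gt(fixed, derived)
})

test_that("summed segment areas agree with trapezoidal integration of the
           densely sampled curve", {
  set.seed(21)
  for (i in 1:10) {
    sl <- randomInstance(n = 30, tied = i %% 2 == 0)
    for (m in ALL_METHODS) {
      curve <- buildPRCurve(sl, m, step = 0.5)
      pts <- curvePoints(curve, pointsPerSegment = 4000)
      expect_lt(abs(trapzPoints(pts) - auprc(curve)), 1e-6)
    }
  }
})

test_that("trapezoidal AUROC equals the tie-aware pair-counting statistic", {
  expect_equal(auroc(prcFixture("perfect")), 1)
  expect_equal(auroc(prcFixture("all_tied")), 0.5)
  set.seed(99)
  for (i in 1:50) {
    sl <- randomInstance(n = sample(5:30, 1), tied = i %% 2 == 0)
    expect_identical(auroc(sl), pairCountAUROC(sl))
  }
})

test_that("random scores concentrate near the prevalence baseline with a
           small positive finite-sample bias", {
  set.seed(17)
  P <- 50; N <- 450
  vals <- replicate(200, {
    auprc(simulateScores(P, N, "random"), method = "continuous_expectation")
  })
  # the estimator's expectation exceeds prevalence slightly (Jensen: the
  # precision TP/(TP+FP) is convex in FP), so assert closeness, not
  # unbiasedness; the P = N = 1 enumeration below pins the effect exactly
  expect_lt(abs(mean(vals) - P / (P + N)), 0.01)
  expect_gt(mean(vals), P / (P + N) - 0.005)

  # exact two-entity enumeration: orderings +- and -+ average to
  # (1 + (1 - log 2))/2, strictly above the prevalence 1/2
  aPlusMinus <- auprc(ScoredLabels(c(2, 1), c(1, 0)),
                      method = "continuous_expectation")
  aMinusPlus <- auprc(ScoredLabels(c(2, 1), c(0, 1)),
                      method = "continuous_expectation")
  expect_equal(aPlusMinus, 1)
  expect_equal(aMinusPlus, 1 - log(2))
  expect_equal((aPlusMinus + aMinusPlus) / 2, (1 + (1 - log(2))) / 2)
  expect_gt((aPlusMinus + aMinusPlus) / 2, 0.5)
})

test_that("profiles with the same method pair coincide on tie-free data", {
  set.seed(8)
  sl <- randomInstance(n = 40, tied = FALSE)
  skAP <- evaluateWithProfile(sl, "scikit-learn (AP)")@auprc
  weka <- evaluateWithProfile(sl, "Weka")@auprc
  expect_equal(skAP, weka)
  # the reference profile is build_prc with derived conventions
  expect_equal(evaluateWithProfile(sl, referenceProfile())@auprc,
               auprc(buildPRCurve(sl, "continuous_expectation")))
})

test_that("order-sensitive tie handling makes AUPRC depend on row order,
           positives-first being larger", {
  # 6-entity single tie group
  posFirst <- ScoredLabels(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  negFirst <- ScoredLabels(rep(0.5, 6), c(0, 0, 0, 1, 1, 1))
  pm <- profileCatalogue("PerfMeas")[[1]]
  aPos <- evaluateWithProfile(posFirst, pm)@auprc
  aNeg <- evaluateWithProfile(negFirst, pm)@auprc
  expect_gt(aPos, aNeg)
  # the reference profile is invariant to the same reordering
  ref <- referenceProfile()
  expect_equal(evaluateWithProfile(posFirst, ref)@auprc,
               evaluateWithProfile(negFirst, ref)@auprc)
})

test_that("profiles without order sensitivity are permutation invariant", {
  set.seed(31)
  sl <- randomInstance(n = 25, tied = TRUE)
  perm <- sample(length(sl))
  shuffled <- ScoredLabels(scoreValues(sl)[perm], trueLabels(sl)[perm])
  for (p in profileCatalogue()) {
    if (p@tieOrderSensitive) next
    expect_equal(evaluateWithProfile(shuffled, p)@auprc,
                 evaluateWithProfile(sl, p)@auprc, info = p@name)
  }
})

test_that("absent negatives give the degenerate precision-1 curve with a
           warning", {
  sl <- ScoredLabels(c(0.9, 0.5, 0.5), c(1, 1, 1))
  expect_warning(curve <- buildPRCurve(sl, "continuous_expectation"),
                 "no negative")
  expect_equal(auprc(curve), 1)
  expect_error(auroc(sl), "no negative")
})

test_that("incomplete-coverage truncation is inert when anchors already
           reach recall 1", {
  # the inclusive >= rule always yields a final anchor at recall 1, so
  # stopping integration there removes no area; the convention still
  # surfaces as an issue flag
  sl <- prcFixture("four_tie_groups")
  ml <- evaluateWithProfile(sl, "MLeval")
  full <- evaluateWithProfile(
    sl, methodProfile("MLeval-full", "linear", "linear"))
  expect_equal(ml@auprc, full@auprc)
  expect_true("incomplete_coverage" %in% ml@issues)
  last <- anchorTable(buildPRCurve(sl, "linear"))[4, ]
  expect_equal(last$recall, 1)
})

test_that("issue flags surface in evaluation reports", {
  sl <- prcFixture("four_tie_groups")
  expect_setequal(evaluateWithProfile(sl, "scikit-learn (linear)")@issues,
                  c("linear_ties", "fixed_start"))
  expect_setequal(evaluateWithProfile(sl, "PerfMeas")@issues,
                  c("incomplete_coverage", "order_dependent_ties"))
  expect_setequal(evaluateWithProfile(sl, "ROCR")@issues,
                  c("fixed_start", "dropped_anchors"))
  expect_length(evaluateWithProfile(sl, "reference")@issues, 0)
  expect_error(evaluateWithProfile(sl, "nonexistent"), "unknown profile")
})

test_that("dropped-anchor export affects curve points but never the area", {
  sl <- prcFixture("no_ties_small")
  curve <- prcties:::.profileCurve(sl, profileCatalogue("ROCR")[[1]])
  full <- curvePoints(curve)
  dropped <- curvePoints(curve, dropAnchors = TRUE)
  expect_lt(nrow(dropped), nrow(full))
  expect_equal(auprc(curve),
               evaluateWithProfile(sl, "ROCR")@auprc)
})
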