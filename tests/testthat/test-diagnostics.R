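## Shared ground truth for the submission-set tests.
diagLabels <- rep(c(1L, 0L), c(5L, 15L))

test_that("a dominating submission is ranked first under every profile", {
  # perfect separation dominates a noisy scorer at every recall
  set.seed(2)
  dominant <- ScoredLabels(c(seq(0.99, 0.9, length.out = 5),
                             seq(0.5, 0.1, length.out = 15)), diagLabels)
  noisy <- ScoredLabels(sample(seq(0.05, 1, by = 0.05), 20), diagLabels)
  rm <- scoreAll(list(dom = dominant, noisy = noisy), profileCatalogue())
  expect_true(all(rankValues(rm)["dom", ] == 1L))

  # an identical duplicate shares rank 1 in every column
  rm2 <- scoreAll(list(a = dominant, b = dominant), profileCatalogue())
  expect_true(all(rankValues(rm2) == 1L))
})

test_that("mismatched label vectors are rejected", {
  a <- ScoredLabels(runif(20), diagLabels)
  b <- ScoredLabels(runif(20), rev(diagLabels))
  expect_error(scoreAll(list(a, b), profileCatalogue()), "mismatched")
  expect_error(scoreAll(list(a = a), profileCatalogue()), "at least 2")
})

test_that("rank flips are exactly the strict pairwise order reversals", {
  # identical columns: no flips
  same <- ScoredLabels(seq(1, 0.05, by = -0.05), diagLabels)
  other <- ScoredLabels(rev(seq(1, 0.05, by = -0.05)), diagLabels)
  rmSame <- scoreAll(list(x = same, y = other),
                     c("Weka", "scikit-learn (AP)", "TorchEval"))
  expect_equal(nrow(rankFlips(rmSame)), 0)

  # hand-built 2x2 value matrix with one reversal
  rm22 <- new("RankMatrix",
              values = matrix(c(0.6, 0.5, 0.4, 0.7), 2, 2,
                              dimnames = list(c("s1", "s2"), c("p1", "p2"))),
              ranks = matrix(c(1L, 2L, 2L, 1L), 2, 2,
                             dimnames = list(c("s1", "s2"), c("p1", "p2"))))
  fl <- rankFlips(rm22)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$profile1, "p1")
  expect_equal(fl$profile2, "p2")

  # a single profile can never flip against itself
  rm1 <- scoreAll(list(x = same, y = other),
                  list(referenceProfile(), referenceProfile()))
  expect_equal(nrow(rankFlips(rm1)), 0)
})

test_that("an all-tied submission outranks a tie-free one under a linear
           profile but not under AP", {
  # heavy ties inflate the linear-interpolation area; AP is unaffected
  labs <- rep(c(1L, 0L), each = 2L)
  allTied <- ScoredLabels(rep(0.5, 4), labs)
  tieFree <- ScoredLabels(c(0.9, 0.6, 0.8, 0.7), labs)  # -,+,+,- by rank
  rm <- scoreAll(list(tied = allTied, free = tieFree),
                 c("scikit-learn (linear)", "scikit-learn (AP)"))
  v <- auprcValues(rm)
  expect_gt(v["tied", 1], v["free", 1])   # linear favors the tied scorer
  expect_lt(v["tied", 2], v["free", 2])   # AP does not
  fl <- rankFlips(rm)
  expect_gte(nrow(fl), 1)
})

test_that("adding a dominated submission preserves existing pair orders", {
  set.seed(12)
  subs <- list(
    a = ScoredLabels(runif(20), diagLabels),
    b = ScoredLabels(runif(20), diagLabels))
  floorSub <- ScoredLabels(c(seq(0.01, 0.05, length.out = 5),
                             seq(0.9, 0.99, length.out = 15)), diagLabels)
  profs <- profileCatalogue(c("reference", "Weka", "PRROC (discrete)"))
  before <- auprcValues(scoreAll(subs, profs))
  after <- auprcValues(scoreAll(c(subs, list(fl = floorSub)), profs))
  expect_equal(after[c("a", "b"), ], before, ignore_attr = TRUE)
  expect_true(all(sign(after["a", ] - after["b", ]) ==
                    sign(before["a", ] - before["b", ])))
})

test_that("profile correlations match direct textbook formulas", {
  set.seed(6)
  subs <- lapply(1:10, function(i) ScoredLabels(runif(20), diagLabels))
  names(subs) <- paste0("s", 1:10)
  profs <- profileCatalogue(c("reference", "scikit-learn (linear)",
                              "Weka", "precrec"))
  rm <- scoreAll(subs, profs)
  co <- profileCorrelations(rm)
  expect_equal(dim(co$pearson), c(4, 4))
  expect_equal(diag(co$pearson), rep(1, 4), ignore_attr = TRUE)
  expect_equal(co$pearson, t(co$pearson))
  # independent recomputation from the definition
  v <- auprcValues(rm)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(co$pearson[a, b], pearson(v[, a], v[, b]),
                 tolerance = 1e-12)
    expect_equal(co$spearman[a, b],
                 pearson(rank(v[, a]), rank(v[, b])), tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are undefined, not zero", {
  labs <- rep(c(1L, 0L), each = 2L)
  # all-tied submissions have identical AUPRC under any single profile
  subs <- list(a = ScoredLabels(rep(0.3, 4), labs),
               b = ScoredLabels(rep(0.5, 4), labs),
               c = ScoredLabels(rep(0.7, 4), labs))
  rm <- scoreAll(subs, c("reference", "Weka"))
  co <- profileCorrelations(rm)
  expect_true(is.na(co$pearson[1, 2]))
  # reversed columns give Spearman -1
  rmRev <- new("RankMatrix",
               values = matrix(c(0.9, 0.5, 0.1, 0.2, 0.6, 0.8), 3, 2,
                               dimnames = list(letters[1:3], c("p", "q"))),
               ranks = matrix(c(1L, 2L, 3L, 3L, 2L, 1L), 3, 2,
                              dimnames = list(letters[1:3], c("p", "q"))))
  expect_equal(profileCorrelations(rmRev)$spearman[1, 2], -1)
})
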