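---
title: "Precision–recall curves under score ties: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision–recall curves under score ties: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **prcties**, the
assumptions behind each connection method and tool profile, the numerical
choices made, and the limitations of the emulation. Every empirical claim
here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not check.

## 1. Data model and anchor points

Input is a set of entities with a real-valued score and a binary label
(`ScoredLabels`). Scores must be finite; higher means "more positive".
Let P and N be the class totals and π = P/(P+N) the prevalence.

The decision rule is **inclusive**: at threshold t, entities with score
≥ t are predicted positive. Sweeping t over the unique score values
yields one **anchor point** per unique score, ordered by descending
score, each with cumulative (TP, FP) and hence
recall = TP/P, precision = TP/(TP+FP). The curve's origin (TP = FP = 0)
is a virtual starting state, never an anchor. Because the last unique
score classifies everything positive, the final anchor always sits at
recall 1 with precision π.

Adjacent anchors A → B delimit a **tie group** with increments
ΔTP = TP_B − TP_A and ΔFP = FP_B − FP_A. Tie-free data is simply the
special case where every group has ΔTP + ΔFP = 1; one code path handles
both.

Tie equality is exact floating-point equality. No epsilon merging is
performed; users who want scores merged at a coarser resolution can
round them first (the CLI exposes `--round-scores` for this, and
`rescale01()` provides an order-preserving affine rescale that leaves
anchors invariant).

## 2. The four connection methods

Between consecutive anchors the curve is not observed; each method is a
convention for filling the gap. The area contribution of each segment is
accumulated into the AUPRC.

**Linear** connects anchors by a straight chord in PR space (a
trapezoid in recall × precision). This is optimistic under ties: recall
and precision do not move linearly together within a tie group, and the
chord passes above the attainable curve whenever precision drops.

**Expectation methods** assume all orderings of the entities within a
tie group are equally likely. After x of the ΔTP tied positives have
been passed (0 ≤ x ≤ ΔTP), the expected number of accompanying false
positives is s·x with s = ΔFP/ΔTP, so the expected precision is

$$ p(x) = \frac{TP_A + x}{TP_A + FP_A + (1+s)\,x}. $$

- **discrete_expectation** samples p(x) at TP steps of size `step`
  (1 by default; 0.5 supported) and sums rectangles of width
  step/P, clamping the final sample to x = ΔTP.
- **continuous_expectation** integrates p(x)/P exactly. With
  b = TP_A + FP_A and a = 1 + s, the closed form is

  $$ \text{area} = \frac{1}{P}\left[\frac{\Delta TP}{a} +
     \left(TP_A - \frac{b}{a}\right)
     \frac{\log\!\left(1 + a\,\Delta TP / b\right)}{a}\right], $$

  computed with `log1p` for accuracy. For the origin segment (b = 0)
  the expectation is the constant ΔTP/(ΔTP+ΔFP) and the area reduces to
  Δr · p. This constant-precision origin is what makes an all-tied
  classifier score exactly π under the expectation methods — the
  defining property of a no-skill baseline, verified in the tests for
  arbitrary class sizes.

**ap** (average precision) assigns each segment a rectangle of height
equal to the *right* anchor's precision:
Σ (Δ recall) · precision_B. It is step-free and never interpolates.

`connectSegment()` exposes a single segment's points and area;
`buildPRCurve()` assembles the full curve. The same area routines back
both, so segment-level oracle tests cover the engine.

## 3. Start conventions

- **derived** (default): the origin segment follows the method's own
  rule (expectation methods use the constant origin expectation; linear
  draws the chord from (0, p₁) which contributes r₁·p₁, numerically the
  same area).
- **fixed01**: non-AP methods draw a linear chord from the fictional
  point (0, 1) to the first anchor, as several tools do. This adds
  r₁·(1 − p₁)/2 area whenever the first anchor's precision p₁ < 1, and
  changes nothing when p₁ = 1. AP's origin rectangle is unaffected by
  the convention.

The fixed start is one of the two mechanisms that inflate an all-tied
classifier: on balanced all-tied data the linear-(0,1) curve scores
0.75 versus the expectation methods' 0.5.

## 4. Tool profiles and issue flags

`MethodProfile` bundles: the method used on tie-free runs
(`noTieMethod`), the method used inside tie groups (`tieMethod`), the
start convention, and three behavioural switches. `profileCatalogue()`
ships a reference profile (continuous expectation throughout, derived
start) plus emulations of 13 tool behaviours. Each profile reports the
conventions it carries as issue flags:

- `linear_ties` — linear interpolation applied across tie groups
  (flagged only when the profile is not order-sensitive, since
  order-sensitive profiles never see multi-entity groups; see below).
- `fixed_start` — the fixed (0, 1) start convention.
- `incomplete_coverage` — the profile does not force a recall-1
  terminal point; integration is bounded at the last anchor derived
  from observed scores. **Design note:** under this package's inclusive
  ≥ rule the last observed anchor always has recall 1, so this
  truncation removes no area. The flag is therefore numerically inert
  here and surfaces only in issue reporting; a perfect classifier
  scores 1.0 under every profile, including those carrying this flag.
  Tools exhibiting this issue in the wild typically pair it with a
  different (exclusive) threshold rule; emulating that rule was out of
  scope because it would change anchor semantics for all profiles.
- `order_dependent_ties` — the profile processes entities in input
  order with a stable sort, so tied entities are broken by row order
  and every group has size 1 (the `noTieMethod` applies throughout).
  AUPRC then depends on row order: putting tied positives first inflates
  it. The reference profile is invariant to such permutations.
- `dropped_anchors` — an export-time convention: emitted curve points
  keep only each segment's right anchor. The AUPRC is unaffected; only
  `curvePoints(..., dropAnchors = TRUE)` output changes. The precise
  point-thinning used by the original tool is not fully documented, so
  this package implements the simplest rule with the same visual
  effect and identical area.

## 5. Diagnostics

`scoreAll()` evaluates a list of submissions (identical label vectors
required) under a set of profiles, producing a `RankMatrix` of AUPRC
values and competition-style ranks (`rank(-x, ties.method = "min")`:
dense, ties share the better rank). `rankFlips()` lists submission
pairs whose order *strictly reverses* between two profiles (ties in
either profile do not count as flips). `profileCorrelations()` returns
Pearson and Spearman correlation matrices across profiles (diagonal
forced to 1; NA where a profile has zero variance).

`auroc()` is included as a tie-robust counterpoint: the tie-aware
trapezoidal form Σ ΔFP·(TP_A + ΔTP/2)/(P·N), which the tests show is
*exactly* (floating-point identical) the Mann–Whitney pair-counting
statistic with half credit for tied pairs. ROC analysis has a single
agreed tie convention; PR analysis does not — that asymmetry is the
package's motivation.

## 6. Synthetic generators

`simulateScores()` provides four models whose defaults are the study
conditions used throughout the tests and the acceptance script:

- `gaussian2`: scores N(separation, 1) for positives, N(0, 1) for
  negatives; `separation = 1` by default. Ties almost surely absent —
  the tie-free control.
- `discretized`: the same scores cut into `nLevels` (default 10)
  equal-width integer bins — the moderate-tie regime.
- `cluster_binary`: binary scores; a predicted-positive cluster of
  `nPredicted` entities (default 10% of all entities) of which
  `tpInPredicted` (default 70% of the cluster) are truly positive —
  the extreme two-anchor regime. The cluster size and composition are
  parameters because no single default suits all class balances.
- `random`: scores Uniform(0, 1) independent of labels — the no-skill
  model for baseline experiments.

All generators accept a `seed` and are byte-reproducible for a given
seed. `prcFixture()` provides small deterministic instances (all-tied,
four tie groups, perfect separation, single trailing positive) used in
the worked examples and tests.

## 7. Numerical choices and verification

- The continuous-expectation closed form uses `log1p`; the test suite
  compares it against adaptive quadrature (`stats::integrate`,
  rel.tol 1e-13) over randomized tie groups and requires agreement
  within 1e-10 (observed: ~1e-16).
- `discrete_expectation` converges to the continuous value as the step
  shrinks; the suite checks monotone error decay over steps 1, 0.1,
  0.01 and an absolute error below 1e-3 at step 0.01.
- `auroc()` is checked for exact equality with pair counting; the terms
  are half-integers divided once at the end, so no tolerance is needed.
- AP, the linear-(0,1) PR area and AUROC are cross-checked against an
  independent external implementation to 1e-12 on tied data.
- Report JSON is written with 17 significant digits so values
  round-trip exactly.

Typical problem sizes exercised are tens to hundreds of entities, with
one baseline identity checked at P = 4012, N = 274380.

## 8. The finite-sample baseline bias

The expectation AUPRC of a *random* scorer concentrates near π but its
mean exceeds π slightly at finite samples: precision TP/(TP+FP) is
convex in FP, so averaging over random orderings lifts the expectation
(Jensen). The effect is exact and large at P = N = 1 — the two
orderings score 1 and 1 − log 2, averaging ≈ 0.653 against π = 0.5 —
and small but resolvable at P = 50, N = 450 (≈ +0.005, reproduced by
`scripts/acceptance.R` as `mc_abs_deviation_from_prevalence`). One
acceptance-level test asserts a mean within Monte-Carlo error of π
exactly; it fails for essentially every seed because of this genuine
bias, and is retained unmodified as documentation of the effect rather
than weakened. The property-level tests assert what is true:
concentration near π with a small positive bias.

## 9. Limitations

- Profiles emulate documented *conventions* (method pair, start,
  coverage, tie ordering, anchor export), not tool internals; versions
  of a tool may differ, and behaviours not captured by these five
  switches (e.g. alternative threshold rules, score preprocessing) are
  out of scope.
- The `incomplete_coverage` flag is informational under this package's
  threshold rule (Section 4).
- The order-sensitive emulation assumes a stable sort of the input
  order; tools with other internal orderings would need their
  permutation applied before evaluation.
- Weighted instances, multiclass problems and confidence intervals for
  AUPRC are not implemented.
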