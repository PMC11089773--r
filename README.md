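# prcties

Precision–recall analysis under score ties, with faithful emulation of the
divergent conventions used by popular evaluation tools.

## The problem

The area under the precision–recall curve (AUPRC) is the standard summary
for classifier performance on imbalanced data, where a no-skill classifier
should score the prevalence π = P/(P+N). But real score vectors contain
ties — discretized outputs, binary predictions, or shared default values —
and at a tied threshold the confusion matrix jumps by more than one entity
at once. Software packages silently differ in how they bridge these jumps,
and the differences are not cosmetic: the same predictions can receive
AUPRC values that differ by large margins, and even the *ranking* of
competing methods can flip depending on which tool scores them. Most
strikingly, several common conventions award an all-tied (constant-score)
classifier far more than the prevalence baseline, rewarding models for
making no distinctions at all.

## Core model

Sweeping the decision threshold over the unique scores (entities with
score ≥ threshold are predicted positive) yields one **anchor point** per
unique score. Adjacent anchors A and B are separated by a **tie group**
with increments ΔTP and ΔFP. The package connects anchors in four ways:

- **linear** — straight chord in PR space (trapezoid), the optimistic
  convention;
- **discrete_expectation** — the expectation curve sampled at TP steps of
  size *tp* (1 or 0.5);
- **continuous_expectation** — the exact integral of the expectation
  curve (reference method);
- **ap** — average precision: rectangles of height equal to the right
  anchor's precision.

The expectation curve assumes all orderings within a tie group are equally
likely. After x of the ΔTP tied positives have been passed, the expected
precision is

    p(x) = (TP_A + x) / (TP_A + FP_A + (1 + s) x),   s = ΔFP / ΔTP,

and the continuous method integrates p(x)/P in closed form (a rational
term plus a `log1p` term). From the curve origin the expectation is the
constant ΔTP/(ΔTP+ΔFP), which makes an all-tied classifier score exactly
the prevalence π — the property a no-skill baseline should have.

Two start conventions are supported: **derived** (the origin segment uses
the method's own rule) and **fixed01** (a linear chord from the fictional
point (0, 1), used by several tools, which inflates the area when the
first anchor's precision is below 1).

`profileCatalogue()` bundles these choices into 14 named **method
profiles** (a reference profile plus emulations of ROCR, Weka,
scikit-learn, PerfMeas, PRROC, TensorFlow, precrec, TorchEval, MLeval and
yardstick variants), each tagged with the conventions it carries:
`linear_ties`, `fixed_start`, `incomplete_coverage`,
`order_dependent_ties`, `dropped_anchors`.

## Worked example

```r
library(prcties)

sl <- simulateScores(12, 48, model = "discretized", nLevels = 5, seed = 42)
sl
#> ScoredLabels: 60 entities (12 positive, 48 negative)
#>   5 unique scores (ties present)

curve <- buildPRCurve(sl, method = "continuous_expectation")
curve
#> PRCurve: method = continuous_expectation, start = derived
#>   5 anchor points, 5 segments; P = 12, N = 48
#>   AUPRC = 0.828 (baseline 0.200)

anchorTable(curve)
#>   threshold tp fp    recall precision
#> 1         5  5  0 0.4166667 1.0000000
#> 2         4 11  6 0.9166667 0.6470588
#> 3         3 12 32 1.0000000 0.2727273
#> 4         2 12 42 1.0000000 0.2222222
#> 5         1 12 48 1.0000000 0.2000000

for (p in c("reference", "ROCR", "scikit-learn (linear)", "Weka", "PerfMeas"))
  cat(sprintf("%-22s %.4f\n", p, evaluateWithProfile(sl, p)@auprc))
#> reference              0.8277
#> ROCR                   0.8337
#> scikit-learn (linear)  0.8668
#> Weka                   0.7629
#> PerfMeas               0.9714
```

The same predictions span 0.76–0.97 across tools. The baseline pathology
is sharper still — an all-tied classifier over 32 positives and 42
negatives (prevalence 0.432):

```r
tied <- ScoredLabels(rep(0.5, 74), rep(c(1L, 0L), c(32L, 42L)))
auprc(tied, method = "continuous_expectation")            # 0.432
auprc(tied, method = "linear", startConvention = "fixed01")  # 0.716
```

Conventions can also reverse rankings between two submissions:

```r
labs <- rep(c(1L, 0L), each = 2)
subs <- list(tied    = ScoredLabels(rep(0.5, 4), labs),
             tieFree = ScoredLabels(c(0.9, 0.6, 0.8, 0.7), labs))
rm <- scoreAll(subs, c("scikit-learn (linear)", "scikit-learn (AP)"))
auprcValues(rm)
#>         scikit-learn (linear) scikit-learn (AP)
#> tied                0.7500000              0.50
#> tieFree             0.7083333              0.75
nrow(rankFlips(rm))   # 1 strict rank reversal
```

A command-line interface over the same functionality is installed at
`system.file("cli", "prc.R", package = "prcties")` with subcommands
`eval`, `curve`, `compare`, `simulate` and `profiles`.

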