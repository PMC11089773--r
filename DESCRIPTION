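Package: prcties
Title: Precision-Recall Curves and AUPRC Under Tied Classification Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs precision-recall curves and computes the area under
    them (AUPRC) with explicit tie-group semantics, under the four methods
    in common use for connecting adjacent anchor points: direct straight
    line, discrete expectation, continuous expectation, and average
    precision. Provides named emulation profiles reproducing the documented
    method combinations and convention flaws of widely used evaluation
    software (fabricated (0,1) start points, incomplete recall coverage,
    input-order-dependent tie handling, dropped anchor points), a
    diagnostics engine quantifying cross-method AUPRC disagreement and
    classifier rank flips, and a synthetic score generator for controlled
    experiments. A reference configuration with order-independent tie
    handling and method-consistent start conventions is included, together
    with trapezoidal AUROC for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
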