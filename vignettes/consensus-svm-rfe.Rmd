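---
title: "Consensus SVM-RFE for paired blood-chemistry panels: models and choices"
author: "consensusRFE maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SVM-RFE for paired blood-chemistry panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusRFE)
```

## The question and the data

Paired serum panels — 41 analytes per subject, measured once before and
once after a months-long ocean voyage — are classified by phase
(`y = +1` pre, `y = -1` post). Analytes that a classifier consistently
relies on to separate the phases are the ones the voyage plausibly
shifted. The package implements the full consensus procedure: a
soft-margin RBF support vector machine, recursive feature elimination
(RFE) with a dual-objective criterion, stability aggregation by
majority-rule voting over resampled partitions, nested
feature-combination accuracy curves, and a paired t-test screen as the
univariate baseline.

The original cohort (170 complete pairs of healthy young men) is
available only on request from its authors, so the package ships a
simulator that regenerates a statistically comparable cohort from the
published per-analyte summary statistics.

## The cohort simulator

`loadReferenceSpec()` assembles, per analyte, Gaussian pre and post
parameters:

* the nine consensus-panel analytes (MAO, PHOS, CK-MB, Ca, LDH, FRUC, K,
  Na, ALB) use the published consensus-summary means and SDs;
* twenty further analytes flagged by the published univariate screen use
  the screen's means and SDs;
* the remaining twelve analytes (TB, UN, UA, GGT, HDL, Mg, TG, TCO2,
  APOA1, APOE, DB, Cl) were reported without any shift; they receive
  synthetic reference-range parameters (adult-male midpoints, labelled
  `null_default` and flagged as synthetic in the shipped file) with
  pre == post, because their only role in the analysis is to carry no
  signal. Where the two published sources disagree on a consensus analyte
  (Na pre-mean 144.50 vs 144.49; LDH post-SD 28.07 vs 28) the consensus
  summary takes precedence. The published TBA screen row duplicates
  FRUC's values — almost certainly a typesetting slip — and is kept as
  printed with its provenance flagged as suspect.

`generateCohort()` draws each subject's pre/post pair of analyte values
from a bivariate normal: `pre = mu_pre + s_pre * Z1`,
`post = mu_post + s_post * (rho * Z1 + sqrt(1 - rho^2) * Z2)`.
Choices worth stating:

* **Within-subject correlation `rho` = 0.5.** The published analysis does
  not report it; a paired design implies a positive value, and because
  every sample vector is classified independently the classification
  results are insensitive to it. It is a constructor argument.
* **Analytes are independent** unless a correlation matrix is supplied
  (`corMatrix`), since no covariance information was published. Real
  panels are correlated (e.g. CK with CK-MB, CHOL with LDL); see
  *Limitations*.
* **No truncation at zero.** All parameterised analytes have means many
  SDs above zero, so negative draws are vanishingly rare; truncating
  would bias the moments the tests check.
* **Determinism.** Identical spec + seed give a bit-identical cohort; the
  generator restores the caller's RNG state.

What passing tests on this cohort do show: the pipeline recovers
dominant standardized shifts, its accuracy estimates behave as the
Gaussian geometry predicts, and every algorithmic invariant holds. What
they cannot show: behaviour under analyte cross-correlation, non-Gaussian
tails, assay drift, or any real-data artefact — conclusions about the
original cohort transfer only insofar as the Gaussian marginals capture
it.

## Classifier and kernel choices

The dual soft-margin problem is solved by the SMO solver in
e1071/libsvm; the package owns standardization, kernel
parameterisation, extraction of the dual solution, and everything
downstream of it. Defaults, all exposed in `kernelConfig()`:

* **Standardization on.** Raw analytes span four orders of magnitude
  (Na ~144 mmol/L vs MAO ~0.85 U/L); an unscaled RBF distance is
  dominated by the large-valued analytes. Features are z-scored by
  training-set statistics, which are stored and reused on test data. A
  constant training column gets scale 1 (it contributes nothing to the
  kernel and scores DJ = 0).
* **C = 1.** The published analysis does not state its penalty; C = 1 is
  the conventional default at this sample-to-feature ratio. Because C and
  the kernel width were never published, the single-split 98.3% accuracy
  printed for one particular partition is not treated as a reproduction
  target anywhere in the package.
* **Automatic gamma = 1 / (p * mean per-feature training variance)** —
  1/p on standardized data — the standard scale-heuristic width.
  Within one RFE run the width is resolved **once, on the starting active
  set** (1/41 for the full panel) and held fixed while features are
  removed. This matters: the elimination criterion takes the absolute
  change of the dual objective, and if the kernel is re-widened as the
  active set shrinks, the multiplicative downdate
  `exp(g * (x_hi - x_ki)^2)` grows for *every* feature, inflating the
  apparent contribution of noise features precisely at the small
  active-set sizes where the final ranking is decided. Holding the
  geometry fixed keeps DJ scores comparable across iterations and is the
  usual practice of not re-tuning hyperparameters inside an RFE loop.
* **Ties and edge cases.** Equal DJ scores remove the higher panel index
  first; a decision value of exactly 0 predicts +1; both conventions are
  arbitrary but fixed and documented.

## Elimination, best subsets and the optimism they carry

Each RFE run records held-out accuracy at every active-set size and keeps
the *smallest* active set attaining the maximum — selected on the test
set, exactly as the consensus procedure it implements. That choice is
optimistically biased (the test set helps pick the subset); the bias is
inherited deliberately, because the subsequent voting step across
partitions is what the procedure relies on for stability, and correcting
it would change the method being implemented. The nested
combination-accuracy curve re-trains per partition restricted to each
prefix of the vote ranking, as the tabulated per-prefix accuracies imply.

## Resampling plan

`makePartitions()` spreads the requested number of partitions as evenly
as possible over the seven train:test ratios (1:1 … 4:1), remainder to
the smallest ratios, so 300 partitions split 43×6 + 42. Rows are assigned
uniformly at random; stratification by label is on by default (the
published analysis is silent; unstratified small splits can degenerate)
and can be switched off. The published analysis splits *vectors*, so a
subject's pre and post rows may land on opposite sides of the split; this
paper-faithful mode is the default, and `bySubject = TRUE` provides a
leakage-free subject-level split for sensitivity analysis. With
within-subject correlation present, vector-level splits let a subject's
training row inform its test row, which is one reason simulated
accuracies sit slightly above the independent-Gaussian Bayes rate
(~95.9% for the nine-analyte panel).

## The t-test baseline

`screenFeatures()` matches pairs by subject identifier and applies the
paired t-test per analyte with no multiple-testing correction, as the
baseline it reproduces did (a Bonferroni option exists, off by default).
Identical pre and post vectors have zero difference variance and are
rejected rather than reported as t = 0: the statistic is 0/0 there. The
published screen's p-values cannot be recomputed from the printed group
means and SDs (the paired-difference SDs were never printed), so they
ship as reference data in `inst/extdata/` and are used only for the
ranking-overlap computation, never asserted as recomputation targets.

## Problem sizes in the packaged runs

The packaged default is R = 50 partitions on a 170-pair cohort — small
enough for a desk run of the full pipeline in about a minute, large
enough for vote fractions to stabilise; the published scale (R = 300) is
one argument away (`repeats = 300`). The test suite exercises the same
code paths at smaller sizes (toy cohorts of 30–100 subjects, 1–21
partitions, 1000-replicate null simulations for the type-I error of the
screen, 20 seeded runs for the informative-feature recovery property).

## Limitations

* Independent Gaussian analytes understate the redundancy of real panels;
  correlated informative analytes would split votes in ways the simulator
  cannot exhibit unless a correlation matrix is supplied.
* Best-subset selection on the test set is optimistic by construction
  (see above); the consensus mean accuracies it feeds are comparable to
  the published figures but are not unbiased generalisation estimates.
* Hyperparameters (C, gamma) use fixed conventional defaults; a small
  grid search utility was considered and deliberately left out of the
  headline pipeline to keep runs strictly comparable.
* Only binary pre/post classification with the RBF kernel (plus a linear
  kernel used as an algebraic cross-check) is supported; multi-class
  problems, alternative kernels and batch-effect modelling are out of
  scope.
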