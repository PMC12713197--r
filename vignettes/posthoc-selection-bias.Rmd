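---
title: "Why low-powered interaction tests manufacture control-group findings"
author: "posthocsim"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posthocsim)
```

## The problem

Two-arm pre/post designs with a waitlist control are the workhorse of trials
where blinding is impossible: psychological therapy, physical rehabilitation,
many neuroimaging interventions. The omnibus analysis is the 2x2
group-by-time interaction — does the active arm change more than the control
arm? — and, wherever the interaction is significant, post-hoc paired tests
within each arm are used to read off the direction of the effect. In
neuroimaging this is done across thousands of regions or voxels with an FDR
correction on the interaction map, and only the surviving regions are probed
post hoc.

That conditioning is a collider. Significance of the interaction depends on
*both* arms' change scores; selecting on it therefore biases the control
arm's noise in the selected subset. When power is low, a trial (or region)
mostly reaches significance because the control arm happened to drift in the
helpful direction, so the post-hoc paired test "confirms" a decline in
untreated participants that was never simulated. This package exists to
quantify that artifact — a Berkson-type selection effect — together with its
twin, the winner's curse: conditional on detection, the estimated interaction
effect overstates the simulated one.

## The generative model

Each simulated trial has two arms of `n_per_group` subjects. For every
subject,

* pre ~ N(0, 1) — scores are in z-units;
* post = pre + w·eps, eps ~ N(0, 1) — `w` (the *retest weight*) scales fresh
  test–retest noise, so the pre/post correlation is 1/sqrt(1 + w²) and the
  change score post − pre is N(0, w²);
* in a *true-effect* trial, a fixed delta is added to every post score of the
  active arm.

A *setting* (grid cell) fixes (n, delta, w) plus the replicate count and the
fraction of replicates carrying a true effect. The full grid crosses
n ∈ {5, …, 50 step 5}, delta ∈ {0.1, …, 1.0 step 0.1} and
w ∈ {0.1, …, 1.0 step 0.1} — 1,000 cells. The reference scale is 100,000
replicates per cell, 10% of them true effects, mimicking a brain in which 10%
of regions genuinely respond; a `reduced` profile (10,000) and a `smoke`
profile (200) exist for desk-scale and CI work. Grid values are carried as
integers scaled by 10 so cell identity never suffers floating-point drift.

The true-effect replicates are a *fixed count*, `round(truth_fraction *
n_reps)`, assigned by a seeded permutation — not Bernoulli draws. The
published denominators (10,000 true / 90,000 null per cell) are exact counts,
and a fixed count removes binomial jitter from the sensitivity denominator.
Every cell owns a private random stream keyed by (base seed, cell index), so
any cell can be regenerated alone, in any order, with bit-identical results;
parallelising over cells cannot change a number.

## The analysis chain

For each replicate the 2x2 repeated-measures interaction F is computed in
closed form as the square of the pooled two-sample t on change scores —
algebraically identical to the mixed-model interaction F for this design
(asserted against a brute-force `aov()` fit in the tests), with df (1,
2n − 2). `beta_hat`, the estimated interaction effect, is the difference in
mean change (active − control). Interaction p-values are then
Benjamini–Hochberg adjusted *within the cell's replicate batch*: one batch
plays the role of one brain-wide family of regions. That family choice
reproduces the published behaviour — the null false-positive rate stays below
0.6% per cell because, at high power, the BH threshold settles near
q·(true discoveries)/m.

Wherever q < 0.05, the post-hoc paired t-test is run on the control arm's
change scores at two-sided alpha = 0.05. The headline *control-arm
false-positive rate* conditions on replicates that simulated a true effect
*and* were detected (scope `true_significant`); the variant pooling *all*
significant replicates and the decline-only variants (mean change < 0) are
computed alongside, since with delta > 0 the selected control changes are
almost all declines and the definitions nearly coincide. We report the
true-significant scope as the default because it is the conditioning under
which the published per-power rates (22.0% at 5% power, 11.4% at 20%, ≈5% at
80%) are recovered; the all-significant scope runs 2–3 percentage points
higher. Post-hoc tests are two-sided and uncorrected by default;
`alpha_posthoc` can be set to 0.025 to emulate a Bonferroni pair of
within-group tests.

## Summaries and meta-models

Per cell: sensitivity (power of the interaction test among true effects),
interaction false-positive rate among nulls, the conditional control-arm
rates above, and the mean effect-size inflation `mean(beta_hat − delta)`
among detected true effects. Rates with empty denominators are `NA`, never
0 — a cell where nothing was detected has no conditional rate, and such cells
are dropped (with counts logged) from downstream fits.

Across cells:

* **Power-binned pooling.** Cells whose sensitivity falls within ±0.025 of a
  target power contribute their selected replicates to one pooled rate
  (replicate-level pooling, not an average of cell rates, so large cells
  weigh more).
* **Sensitivity regression.** OLS of per-cell sensitivity on delta, w and n;
  slopes are in sensitivity fraction per unit. The residual df is
  structurally `n_cells − 4` (996 on the full grid).
* **Curve fits.** The control-FP rate against sensitivity follows
  y = a/(sqrt(x) + b) + c; effect-size inflation against sensitivity follows
  y = a/(x² + b) + c. Both are fitted by multi-start Levenberg–Marquardt:
  the objective is multimodal in b, so b is started on a log-spaced grid
  (7 values spanning the scale of the transformed predictor) and, for each
  start, a and c are initialised at their *exact* conditional least-squares
  values — the model is linear in (a, c) given b — which is a
  better-conditioned start than any finite-difference slope heuristic. The
  constraint b > 0 keeps the pole outside the data domain. Fits are
  unweighted by default (a replicate-count-weighted variant is available via
  the `weights` argument); x and y are both on the fraction scale, under
  which the fitted curve evaluated at 80% power lands at ≈0.05, consistent
  with the quoted per-power sequence. For the inflation curve the x-scale the
  original analysis used is ambiguous (the published coefficients only bend
  below sensitivity ≈ 10⁻³ on the fraction scale), so the runner fits and
  reports both the fraction- and percent-scale variants rather than asserting
  either.

## Numerical and degenerate-input choices

* `w = 0` is admitted only as a test fixture: every change score is then
  constant, the pooled variance is zero and the statistics are undefined.
  Such replicates raise classed `degenerate_variance_error`s trial-wise, are
  flagged and excluded from batch denominators with a warning, and cannot
  occur on the published grid (w ≥ 0.1).
* The batch kernel (C++) reproduces the scalar R formulas bit for bit
  (long-double accumulation in the same order), so the vectorized grid run
  and the per-trial functions are interchangeable — a property the tests
  assert with `expect_identical`.
* BH q-values, `lm`, `aov` power oracles and `nlsLM` come from their standard
  implementations; the package authors only the simulation-specific layers.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full 1,000-cell grid at
the reference scale of 100,000 replicates per cell (10⁸ trials, roughly ten
minutes on one core thanks to the closed-form batch kernel); smaller
fixtures (hundreds to tens of thousands of replicates) exercise the
individual components. At the reference scale the maximum per-cell null
false-positive rate lands at ≈0.6%, the regression slopes reproduce to
±0.001, and the power-curve adjusted R² lands within a few hundredths of
0.91. Reduced-scale runs preserve all qualitative conclusions but
inflate two statistics predictably: a max over 1,000 noisy binomial
proportions creeps upward, and the power-curve R² drops because low-power
cells estimate their conditional rate from a handful of selected replicates.

## What the generator does and does not emulate

It emulates exactly the tabular abstraction of a multi-region trial: many
independent replicates per design, a fixed 10% prevalence of true effects,
homogeneous Gaussian noise, and FDR correction within the replicate family.
It does not emulate spatial correlation between regions, non-Gaussian or
heteroscedastic noise, dropout or missing data, placebo responses, or
cluster-level inference on images — so a green suite here demonstrates the
*statistical selection mechanism*, not the magnitude of the artifact in any
particular imaging pipeline. Voxel-level demonstrations on real scans
require participant data and a full imaging pipeline, and are out of scope
here.

## Limitations

* The design is fixed at 2 groups x 2 times; no covariates, sphericity
  issues or k-level factors (the closed-form F identity is specific to 2x2).
* FDR families other than "one cell's replicate batch" (e.g. pooling the
  whole grid) are not offered; the per-cell family is what makes per-cell
  rates interpretable.
* Monte-Carlo error at the reduced profile is material for max-type and
  small-denominator statistics, as quantified above.
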