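---
title: "Modelling weather-driven catechin accumulation with meteocat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weather-driven catechin accumulation with meteocat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meteocat)
```

## The problem and the data layout

Tea catechins respond strongly to the weather of the growing season,
and the two catechin groups respond in opposite directions: galloylated
(esterified) catechins such as EGCG accumulate under hot, rainy
conditions, while the non-esterified monomers (EGC, C, EC) prefer cool,
dry ones. `meteocat` models this with a chain of standard chemometric
steps over a simple tabular design: one record per plantation site and
season, eight season-aggregate meteorological factors as predictors,
and the seven catechin monomer concentrations (percent dry mass) as
responses, optionally accompanied by qPCR expression of flavonoid
biosynthesis genes.

The package assumes replicate field measurements have already been
averaged to per-(site, season) means; `average_replicates()` does this
when raw replicate rows are supplied.

## Meteorological features

Two of the eight factors are derived statistics with conventions worth
stating precisely:

* **Effective accumulated temperature (EAT).** The daily excess of mean
  air temperature over the biological zero of tea (10 °C), averaged
  over the observation period. By default days below the biological
  zero contribute zero rather than a negative excess — the usual
  growing-degree convention, and consistent with all observed seasonal
  EAT values being positive — but `clip_negative = FALSE` gives the
  literal signed average. Note that the reference optimisation operates
  on EAT values in the hundreds (223.5–553.7); the package treats the
  EAT column as an opaque bounded covariate and does not attempt to
  reconcile its aggregation scale with the daily formula.
* **Rainy-day rainfall.** Total rainfall divided by the number of days
  with measurable precipitation, so dry days do not dilute the average.
  "Measurable" defaults to strictly positive, configurable (e.g.
  0.1 mm) for stations with a trace floor. A fully dry period returns 0
  with a warning instead of dividing by zero.

## The synthetic survey generator

The generator emulates the study conditions the analysis expects: 10
sites × 3 seasons (30 records) by default.

* **Weather** is drawn independently and uniformly per factor within a
  per-factor box, then each record's three temperature values are
  sorted so that min ≤ avg ≤ max. The default box is the reference
  optimisation box, with one change: the minimum-temperature interval
  in that box is a single point (every published optimum shares
  −3.6 °C), and a constant predictor is unidentifiable in any
  regression, so the generator widens it to [−3.6, 15] °C — a realistic
  spread of seasonal night minima for a subtropical tea region. The
  optimizer fixture `tieguanyin_factor_box()` keeps the degenerate
  interval exactly.
* **Catechins** are generated from the reference linear equations plus
  Gaussian noise and floored at zero (concentrations cannot be
  negative); the flooring count is reported and attached so tests can
  assert it stays rare. The default noise level is ten times each
  response's published calibration RMSEC: the published RMSEC values
  (e.g. 0.016 % for EGCG, a response spanning several percent) are far
  below plausible field variability, so they are used only as relative
  magnitudes. This is a stated convention, not an estimate of the
  original study's noise.
* **qPCR Ct values** encode a log2-linear response of each linked gene
  to the standardized factors with Gaussian log2 noise, constructed so
  that the 2^−ΔΔCt chain recovers exactly the intended relative
  expressions.

Uniform independent factors are deliberately simpler than real weather:
they carry none of the strong temperature/EAT collinearity or
season–site structure of field data. Passing tests on synthetic data
therefore demonstrate correctness of the computations and
identifiability at the study scale, not robustness to real-world
collinearity; the generator's bounds are the only part of the real
study's structure it preserves.

## PLS screening and VIP

Each response is fitted separately (PLS1) on the eight autoscaled
factors — autoscaling is the chemometrics default when predictors mix
units as different as millimetres and lux, and importance scores are
computed in the scaled space. Components are extracted by sequential
NIPALS (deterministic; for a single response each component is a
closed-form covariance direction, no iteration). The component count is
chosen by leave-one-out RMSECV, capped at min(n − 1, 8), ties toward
fewer components.

Variable importance uses Wold's VIP — the de-facto standard matching
SPSS/SIMCA conventions — with `SS_a = q_a² t_a't_a` the response
variance explained by component *a*. The normalization `Σ_j VIP_j² = 8`
holds by construction, and screening keeps factors with VIP strictly
greater than 1. With full components PLS1 reproduces the least-squares
solution, which the tests use as an external anchor (alongside a
cross-check against `mixOmics`).

Raw responses are the default; `log2_responses = TRUE` is available for
expression responses, whose natural scale is multiplicative.

## Per-catechin regression and validation

All eight factors enter every calibration model, mirroring the
published equations, which retain all eight terms regardless of VIP
screening. RMSEC is the training residual RMS; RMSECV is leave-one-out
by default (k-fold with a mandatory seed otherwise, and k = n
reproduces leave-one-out exactly); RMSEP uses a seeded 70/30 split
stratified by season, since no split is prescribed by the reference
study. Predictions may fall below zero outside the calibrated region;
they are flagged with a warning and never silently clipped, because
clipping would hide extrapolation.

Rank-deficient designs abort with the collinear columns named rather
than silently dropping terms.

## The grouped optimization

The optimization asks: within the observed weather box, which
conditions maximise a catechin's predicted concentration while keeping
its group partners (TEC or TNEC) inside observed bounds? Objective and
constraints are all linear, so the optimum lies at a vertex of the
feasible polytope. With 8 variables and at most six threshold rows the
complete candidate vertex set (every combination of binding threshold
rows, free-variable subsets and box-bound assignments) is small enough
to enumerate exactly, which is what `solve_lp()` does — no iterative
solver, no convergence tolerance, and deterministic tie-breaking toward
the lexicographically smallest optimal conditions in canonical factor
order. Box-only problems reduce to the coefficient sign rule (factor at
its upper bound iff its slope is positive). Feasibility at the reported
optimum is enforced to 1e-9 (relative to each bound's magnitude), and
the binding constraints are reported so users can see which weather
limits and group thresholds actually pin the optimum.

Infeasible threshold systems return a certificate naming a violated
constraint when a single row is responsible; non-finite boxes in a
paying direction return status `unbounded`.

Two reference points deserve comment. The published C optimum is
exactly the box vertex selected by the sign rule, and the LP reproduces
every coordinate; its objective from the printed rounded coefficients
is 4.61 %, within 1 % of the published 4.58 % (which came from
unrounded internals). The published EGCG optimum, in contrast, is *not*
a sign-consistent box vertex (its EAT and irradiance coordinates sit at
bounds the EGCG slopes would not choose), implying binding group
constraints or importance weighting in the original optimisation run
whose exact setup is not recoverable. The package therefore treats the
published optima as evaluation points for the reference equations and
validates its own solver by oracle equivalence — a 256-vertex
brute-force enumeration for box problems and an independent HiGHS
solution for grouped problems — rather than by matching the published
EGCG argmax. An optional VIP-weighted objective is exposed through the
coefficient table interface for users who want to explore
importance-weighted variants.

## qPCR processing

Relative expression follows the 2^−ΔΔCt method against GAPDH and a
reference plantation (BM by default). Normalization is per season by
default — each season's samples against the reference site's record of
the same season — with a global single-record reference behind a flag;
per-season is the natural reading when all three seasons are displayed
on a common unit scale. Replicate Ct rows are averaged before the ΔΔCt
chain. Amplification efficiency uses the standard-curve convention:
regress Ct on log10 of template amount (the reciprocal of the dilution
factor), then `E = 10^(−1/slope) − 1`, so a perfectly doubling assay
(slope −3.3219 cycles/decade) has efficiency exactly 1; slopes outside
(−10, −1) warn as implausible.

Heatmap-style reports need a reproducible row/column order, not a
rendering: `hclust_leaf_order()` clusters on Euclidean distances
(average linkage by default; the original analysis does not state a
linkage) and makes the leaf order deterministic by placing, at every
merge, the subtree containing the alphabetically smallest label first.
Tests verify the order against an independent brute-force UPGMA
implementation.

## Correlation and PCA

Pearson correlations carry two-sided t-test p-values and star codes
with closed upper boundaries (`*` for 0.01 < p ≤ 0.05, `**` for
0.001 < p ≤ 0.01, `***` for p ≤ 0.001). No multiple-testing correction
is applied by default, matching common practice in this literature;
Benjamini–Hochberg is a flag. PCA standardizes variables by default
(correlation-matrix PCA) — consistent with component standard
deviations near √(7 · share) for seven unit-variance variables — and
fixes the sign of each loading vector by making its largest-magnitude
entry positive, since principal axes are sign-arbitrary. All 30
site-season samples enter pooled; season-mean PCA can be run by
averaging first.

## Numerical conventions and test scale

* Feasibility/tie tolerance in the optimizer: 1e-9, scaled by bound
  magnitude; candidate systems are solved by QR with its scale-aware
  rank test.
* CSV round-trips serialise numerics at 15 significant digits, lossless
  to 1e-9 relative.
* Concentrations are reported at 2 decimals where mirroring the
  published tables; full precision is kept internally.
* Test problem sizes: the identifiability and recovery checks run at
  the survey size (n = 30) and ten times it (n = 300); the solver
  equivalence suite uses 200 random box problems; screening power uses
  100 replicates at n = 300 with 2 components. These sizes were chosen
  as the smallest that make the respective properties sharp.

## Known limitations

* The reference coefficient table is the published rounded one; small
  discrepancies against values computed from unrounded internals (the
  4.58 vs 4.61 case) are inherent and documented where they occur.
* The original study's raw survey data are not deposited, so its
  data-dependent outputs (printed error metrics, PCA variance shares,
  VIP values, heatmap figures) are not reproducible here; the package
  covers that ground with property-based tests and synthetic-mode
  demonstrations instead.
* The generator does not simulate daily weather series; it produces
  season-aggregate factors directly, and its independence assumption
  understates real collinearity between temperature factors and EAT.
* The optimizer is exact only because the models are linear; it is not
  a general nonlinear or multi-objective optimiser.
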