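---
title: "Weighted effect coding and orthogonal interaction contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted effect coding and orthogonal interaction contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wecint)
```

## The problem

A regression on categorical predictors needs a parameterization, and the
choice decides what the coefficients mean. With **dummy coding** (0/1
indicators) each coefficient contrasts a level against a chosen reference
category — fine when there is a directional hypothesis about specific
subgroups, arbitrary when there is not. With **effect coding** (the
omitted level coded −1) coefficients are deviations from the *unweighted*
mean of level effects, the natural baseline for balanced experiments
where every cell holds the same number of observations.

Observational data are almost never balanced. When cell sizes differ —
and the imbalance is a real feature of the target population rather than
sampling noise — the unweighted grand mean is an average over a
population that does not exist. **Weighted effect coding (WEC)** fixes
the baseline: the omitted level of a K-level factor is coded
−n_k/n_r in the column for level k (n_k and n_r the level counts, r the
omitted level). Every column then sums to zero *over observations*, the
intercept is the count-weighted (i.e. ordinary arithmetic) sample mean,
and each coefficient is that level's deviation from it. Coefficients for
the omitted level are not lost: they are recovered by refitting with a
different omitted level, or equivalently from the constraint
Σ_k n_k b_k = 0.

## Interaction contrasts that leave the main effects alone

The package's central construction is the WEC *interaction* column for a
two-way K × L cross-classification. Dummy and effect interaction columns
are elementwise products of the main-effect columns; a WEC interaction
column deliberately is not. The column for the level pair (k, l) is
constant within cells and takes only four non-zero values:

| cell | code |
|------|------|
| (k, l) | 1 |
| (k, r_B) | −n_kl / n_{k r_B} |
| (r_A, l) | −n_kl / n_{r_A l} |
| (r_A, r_B) | +n_kl / n_{r_A r_B} |

with r_A, r_B the omitted levels and n with two subscripts the cell
counts. Summed over observations with these weights, the column has mean
zero and zero dot product with the intercept and with every WEC
main-effect column of both factors — an algebraic identity in the cell
counts, not an approximation (each product telescopes to
n_kl − n_kl − n_kl + n_kl on the intercept and to ±n_k n_kl/n_r pairs on
the mains). Because the interaction block is orthogonal to the additive
block, adding it changes neither the intercept nor any main effect of an
identity-link fit: the interaction coefficients are pure extras, the
deviation of each cell mean from what the additive model already
predicts. Their count-weighted sums vanish along every row and every
column of the cell grid (their unweighted sums generally do not — that
is effect coding's constraint, not WEC's).

When all cells hold equal counts every ratio −n_kl/n_.. collapses to −1
and the WEC columns equal the effect-coded columns entrywise, so WEC is
a strict generalization of effect coding to unbalanced data.

The four-cell pattern is stated for a 2 × 3 layout in the literature the
package follows; the K × L form implemented here applies the same
pattern to every non-omitted level pair. No printed general formula
exists to compare against, so the generalization is validated by its
defining properties instead: the test suite checks zero column sums and
exact orthogonality to the intercept and mains on random unbalanced
tables for all K, L ∈ {2, 3, 4}, against a brute-force cell-level
summation oracle.

## Fitting: raw observations or sufficient statistics

All coded predictors are constant within cells, so least-squares
coefficients depend on the data only through cell counts and cell means.
`fit_ols_raw()` fits from observations; `fit_ols_grouped()` fits the
identical coefficients from a `cell_table` alone, by count-weighted
least squares on one pseudo-observation per cell. The grouped route is
what makes published tables executable: printed counts plus printed
saturated coefficients determine the cell means, and the cell means
determine every other column of the table. Grouped fits report no
standard errors — the within-cell variance is not a function of counts
and means.

`fit_glm()` fits any of the coded designs by maximum likelihood
(gaussian or binomial/logit). With the identity link it reproduces OLS.
With the logit link WEC coefficients are deviations on the log-odds
scale and relate to the odds, not to the probability itself; column
orthogonality does not carry over to information-orthogonality, so the
main-effect invariance is *not* asserted for non-identity links —
`verify_invariance()` reports the observed change instead of assuming
it away. The same caution applies to controls: a control variable
correlated with the interaction columns can shift the main effects
between the additive and the interaction model, so invariance is
asserted only for identity-link fits without controls.

## The built-in worked example

The package ships the cell counts and printed coefficients of a
published OLS worked example: body mass index (BMI) regressed on
parenthood (with children, n = 2254 / childless, n = 1060) and age group
(young 610 / middle 2111 / older 593) in a pooled sample of 3314 Dutch
adults, under all three codings, with and without interactions.
`reproduce_table4()` reconstructs the six cell means by summing the
printed saturated dummy coefficients (intercept 24.88 → cell means
24.88, 25.34, 26.10, 22.96, 24.64, 25.39), refits everything by grouped
weighted least squares, completes the omitted categories, and compares
all 46 coefficients against their printed values.

The pass tolerance is 0.03 BMI points. The printed inputs are rounded to
two decimals, so each reconstructed cell mean carries up to ±0.005 per
summed coefficient (up to four terms); the count-weighted refits mix
these errors without amplifying them beyond their extrema, bounding the
achievable agreement near ±0.02. The observed maximum deviation is
about 0.006. Two hand-computable checks are held to exact arithmetic
instead, because they are plain sums of printed numbers: the fitted
childless-young cell under effect coding with interactions
(24.88 − 0.56 − 0.97 − 0.41 = 22.94) and the dummy-coded contrast for
the childless middle-aged (−1.92 + 1.22 = −0.7). What the fixture cannot
reproduce are the printed t-values and explained variances: those need
the raw microdata, not just counts and means, and the package makes no
claim about them.

## The synthetic-data generator

`simulation_config()` / `generate_dataset()` produce unbalanced
two-factor datasets with *fixed* cell counts (design, not random),
configured cell means, homoskedastic normal within-cell noise, and
optionally a standard-normal control with a linear slope. A single
integer seed drives one generator stream with cells drawn in sorted
(level A, level B) order, so a seed reproduces a dataset bit for bit.
`balanced_counterpart()` raises every cell to the maximum count, which
is what the scheme-collapse tests use.

The generator emulates what matters for the estimators — imbalance,
known cell means, within-cell noise — and deliberately nothing else: no
heteroskedasticity, no non-normal errors, no missingness mechanism, no
survey weights. Passing tests therefore demonstrate the algebraic and
statistical correctness of the coding and fitting machinery under the
homoskedastic linear model; they do not certify behaviour under
violations of it.

## Numerical and design choices

* **Solver.** All fits go through QR decomposition (`lm.fit`,
  `lm.wfit`, `glm.fit`), never the normal equations; relative rank
  tolerance 1e-10, with rank deficiency reported as an error naming the
  collinear columns.
* **Default omitted level.** `"auto"` picks the most frequent level
  (largest n_r makes the −n_k/n_r weights smallest and the completed
  reference estimate most stable); ties break to the earliest level.
  Always overridable — the built-in example uses the published
  reference choices, which follow no stated rule.
* **Level order.** First appearance in the data unless declared; all
  outputs are keyed by label, never by position.
* **Completion.** Refit with a different omitted level is the primary
  method; the sum-to-zero constraint is an independent cross-check, and
  disagreement beyond 1e-6 (absolute) is an error, since the two routes
  agree to machine precision when the coding is correct.
* **Weights.** Stored as full-precision ratios, never rounded. By
  default computed from the analysis sample; externally supplied (e.g.
  population) counts are accepted, since the case for weighting rests on
  the imbalance being real in the target population.
* **Empty cells.** Allowed for dummy and effect columns; an error naming
  the cell for WEC interaction columns, whose weights divide by the four
  referenced cell counts.
* **Missing values.** Listwise deletion with a message reporting the
  number of dropped rows.
* **Separation.** A binomial fit whose fitted probabilities reach the
  0/1 boundary (a cell with constant outcome) is reported as
  non-convergence with the iteration count, not returned as a finite
  but meaningless estimate.

Test problem sizes are kept small — random tables up to 4 × 4, a few
hundred observations per synthetic dataset, 50 replicates in the
bias check — because every property tested is either exact algebra
(orthogonality, collapse, invariance) or an identity between two
computation routes, neither of which gains anything from scale.

## Limitations

Two-way cross-classifications only; no three-way layouts or survey
weights. Interactions between a weighted-effect-coded factor and a
continuous covariate are not implemented. Standard errors are available
for raw-data fits only, and the completed (reference-category)
estimates carry no standard errors at all from grouped fits. The
main-effect invariance is a property of identity-link models without
controls; for logit models and controlled models the verifier measures
the change, it does not promise zero.
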