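---
title: "Benchmarking variable selection for descriptor-table regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variable selection for descriptor-table regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In QSAR/QSPR modelling a continuous property or activity $y$ is regressed on
tens to hundreds of computed molecular descriptors (or spectral channels)
$X$. Variable selection is supposed to improve both prediction and
interpretability by removing descriptors unrelated to $y$ — but judging a
selection method by the accuracy of a *single* downstream model confounds
the selection with the model choice, and the count of selected variables
alone says nothing about how many of them are noise.

varselbench scores every selection by three indicators:

1. **Predictive quality** — the 10th percentile of the test-set mean
   absolute errors, $\mathrm{MAE} = \frac{1}{m}\sum_i |y_i - \hat y_i|$,
   achieved by a suite of 24 regression configurations fitted on the
   selected columns. Taking a low quantile of many models asks "how well do
   these variables predict, given a sensible model choice", not "how well
   does one arbitrary model do".
2. **Ratio of selected originals** — selected original descriptors divided
   by all original descriptors.
3. **Ratio of selected probes** — before selection, the table is spiked
   with as many uniform(0,1) "random probe" columns as there are original
   descriptors; the fraction of probes a selector picks (relative to the
   original count) directly measures its false-selection tendency, which
   the selected-variable count alone cannot reveal.

## The selectors

* **LASSO** minimises $\sum_i (y_i - x_i b)^2 + \lambda \sum_j |b_j|$;
  variables with exactly-zero coefficients drop out. The penalty is chosen
  from the grid $2^{-15}, \dots, 2^{-1}$ by 5-fold cross-validated $r^2$,
  with ties resolved toward the smaller penalty (less deletion). The grid
  and objective match scikit-learn's parameterisation
  ($\frac{1}{2m}\mathrm{RSS} + \lambda \|b\|_1$, which is also glmnet's),
  so the penalty values are directly comparable across implementations.
* **GAPLS / GASVR** are wrapper selectors: a genetic algorithm over
  real-valued chromosomes in $[0,1]^p$ (binarised at 0.5, inclusion on
  $\ge$) maximises the pooled out-of-fold 5-fold CV $r^2$ of a PLS
  regression (component count chosen by the same CV, capped at 30) or of a
  Gaussian-kernel $\varepsilon$-SVR. GASVR appends three genes decoding
  $\log_2 C \in [-5,10]$, $\log_2 \varepsilon \in [-10,0]$ and
  $\log_2 \gamma \in [-20,10]$, so the hyperparameters evolve with the
  mask. ("Tolerance" in SVR parlance is read as the $\varepsilon$-tube.)
* **Boruta** compares each descriptor's random-forest impurity importance
  with shadow features — per-column permutations of the descriptors — and
  decides each variable by an exact two-sided binomial test
  ($\alpha = 0.05$, tails at $\alpha/2$) on its hit count over iterations.
  A hit means strictly exceeding the $p$-percentile of the shadow
  importances; classically $p = 100$ (the shadow maximum).
* **r-Boruta** replaces the fixed $p = 100$ with a chance-correlation
  calibration: generate a large number (default 10,000) of standard-normal
  columns, take $100 \times \max |r|$ of their Pearson correlations with
  $y$. At small sample sizes unrelated variables correlate with $y$ by
  accident, the shadow maximum becomes a harsh bar, and plain Boruta
  over-deletes; the calibrated percentile lowers the bar exactly as much
  as chance correlation warrants.

## GA and Boruta mechanics, as implemented

The GA uses tournament selection (size 3), uniform crossover (pair
probability 0.9, per-gene swap 0.5), per-gene uniform-reset mutation
(probability $1/\mathrm{length}$) and elitism of one, with population 100
and 50 generations by default. Fitness values are cached by decoded mask
(plus decoded SVR parameters), and the elitist best-fitness trajectory is
monotone non-decreasing by construction — both properties are asserted in
the tests. Because the optimum of a CV-$r^2$ objective often includes a
few noise columns, GA selections are inherently seed-dependent; that
variability is part of what the benchmark measures.

Boruta re-shuffles the shadows at **every** iteration (the canonical
algorithm), removes rejected columns from subsequent forests (their hit
counts freeze), and lets confirmed columns keep competing. Forests use 500
trees and impurity importance; the loop stops when nothing is tentative or
after 100 iterations, and still-tentative columns are *not* selected under
the default policy. The shadow percentile interpolates linearly between
order statistics, so $p = 100$ is exactly the maximum; boundary equality
with the reference is not a hit.

## The regression suite

The full suite holds 24 configurations: PLS, ridge, LASSO, elastic net,
SVR with linear and Gaussian kernels, a decision tree, a random forest,
Gaussian process regression under 11 registered kernels (linear, RBF,
Matérn 3/2, Matérn 5/2, rational quadratic, each also with an added
white-noise component, plus a linear+RBF sum), four gradient-boosting
configurations, and a single-hidden-layer neural network. Each
configuration tunes a small visible grid by seeded 5-fold CV (choosing the
smallest CV MAE), refits, and reports the test MAE in **original response
units** (the autoscaling of $X$ and $y$ by training statistics is inverted
before the error is computed).

Two honest substitutions are worth naming. The four boosting
configurations all run on the xgboost backend: a classic slow-learning
shallow GBDT, a regularised subsampling variant, a histogram/loss-guided
(leaf-wise) variant, and a depth-wise strongly L2-regularised variant —
they emulate the behavioural spread of the popular boosting libraries
rather than binding to each one. The neural-network family is a
single-hidden-layer feed-forward net (size and weight decay tuned);
deeper architectures would add little on tables of this size. The GPR is
a direct Cholesky implementation with a median-heuristic lengthscale
(multiplier tuned over $\{0.5, 1, 2\}$) and tuned observation noise.

A `"fast"` 8-configuration profile (PLS, ridge, LASSO, EN, Gaussian SVR,
tree, forest, RBF-GPR) exists for routine benchmarking; the percentile
reducer is profile-agnostic, and a failed configuration is excluded from
the percentile with a warning rather than voiding the run. A `"none"`
profile skips the suite for selection-ratio studies.

## Preprocessing

The pipeline mirrors standard chemometric practice: a seeded random
70/30 split (`round(0.7 n)` training samples — symmetric rounding, since
only percentages are conventional); removal of columns whose most frequent
training value reaches 80% (exact equality, no binning); removal of the
later column of any training pair with $|r| \ge 1 - 10^{-12}$ (first
occurrence survives; the tolerance absorbs floating-point error in an
otherwise exact rule); probe spiking; autoscaling by training statistics.
All filters are decided on the training partition only. Probes are drawn
independently for the training and test rows so that models containing
wrongly-selected probes can still be evaluated on test data.

## The synthetic generator

`synthetic_spec()` emulates a mid-sized QSAR descriptor table: 200
samples, 10 informative descriptors drawn from an equicorrelated
multivariate normal (pairwise $\rho = 0.3$; a single-factor construction,
positive-definite for any $\rho < 1$) with geometrically decaying effect
sizes from 3 down to 0.3, 65 independent standard-normal noise
descriptors, and unit observation noise. The decay gives a realistic mix
of strong and marginal signals; the within-block correlation reflects the
redundancy of computed descriptor sets. An optional
`quadratic_interaction` response adds the product of the first two
informative columns for studying nonlinear selectors.

What the generator does **not** emulate: heavy-tailed or discrete
descriptor distributions, the smooth channel-to-channel correlation of NIR
spectra, train/test distribution shift, and measurement error in $X$.
Passing benchmarks here therefore demonstrate correctness of the machinery
and qualitative method behaviour — not performance claims on real
chemical data.

## Numerical choices and degenerate inputs

* Pooled out-of-fold $r^2$ (one number over all held-out predictions, no
  per-fold averaging) is used everywhere a CV $r^2$ is needed.
* CV folds are seeded shuffled K-folds; every stochastic component
  (splits, probes, GA, forests, calibration draws) takes an explicit seed,
  and repeat $r$ of a benchmark uses `base_seed + r * 10007`.
* PLS on a single column reduces to least squares on that column (the
  one-component PLS solution); a constant training response short-circuits
  every suite family to the exact intercept-only model; single-column
  designs are padded with a zero column for the glmnet families.
* The GPR adds jitter $10^{-8}$ to the kernel diagonal before the
  Cholesky factorisation.
* Empty selections never raise: selectors return a flagged empty result,
  and the benchmark emits a record with zero ratios and a missing MAE.

## Problem sizes in the shipped checks

The test-suite benchmarks run the default 200 × 150 synthetic table for
10 repeats of LASSO/Boruta/r-Boruta, and the acceptance script runs 3
repeats of all five selectors with the fast suite plus a reduced GA
(population 24, 15 generations, PLS components capped at 10) — sizes at
which the full protocol, including the brute-force oracles, completes
comfortably on a single CPU while leaving every algorithmic path
exercised at its defaults.

## Known limitations

* GA defaults (population 100, generations 50) are common practice, not a
  tuned optimum; wrapper results on large descriptor sets remain
  seed-sensitive by nature.
* The r-Boruta calibration uses standard-normal random columns and Pearson
  correlation; the spiked probes are uniform(0,1). The two conventions are
  deliberate and configurable, but mixing them means the calibration is
  not a probe-selection rate estimate.
* No multiple-testing correction is applied across columns in the Boruta
  binomial decisions (each column is tested on its own hit count).
* The suite's 24 configurations fix their tuning grids; they are meant as
  a stable measuring instrument, not as the best attainable model per
  family.
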