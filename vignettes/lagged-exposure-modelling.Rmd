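---
title: "Modelling cancer incidence from lagged PM2.5 exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cancer incidence from lagged PM2.5 exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagrisk)
```

## The data model

The unit of analysis is the region-year. Each row carries ten exposure
covariates `lag0`...`lag9` — the annual-mean PM2.5 concentration (ug/m3) in
the outcome year and each of the nine preceding calendar years — and one
response, the cancer incidence rate (new cases per 100,000). Carcinogenesis
is slow, so incidence in year *y* is expected to reflect exposure over the
preceding decade rather than year *y* alone; the ten lag columns make that
exposure history explicit.

Because `lagL` in year *y* and `lag(L-1)` in year *y - 1* are literally the
same annual mean, and annual pollution levels are strongly persistent, the
lag columns are severely collinear by construction. That collinearity is the
central statistical difficulty the package is built around: it inflates OLS
coefficient variances without biasing predictions, so the package pairs
explicit diagnostics with three predictors that tolerate it.

## The synthetic generator

Registry incidence data are generally not public, so `generate_panel()` and
`generate_incidence()` provide a ground-truth substitute with the same
statistical structure:

- each region's annual exposure series is a stationary Gaussian AR(1) with
  marginal mean `exposure_mean`, marginal sd `exposure_sd` and autocorrelation
  `ar_rho`; the lag columns are read off this series by a sliding window, so
  inter-lag correlation decays approximately as `ar_rho^d` with lag distance
  `d`;
- incidence is `intercept + sum_L w_L * lagL + N(0, noise_sd)`, floored at 0,
  with the weight vector `w` known to the caller for parameter-recovery
  checks.

Defaults describe a mid-sized registry panel: 30 regions by 5 outcome years
(150 region-years), exposures around 55 ug/m3 with sd 12 — annual means
typical of a heavily industrialised province in the 2010s — `ar_rho = 0.95`,
which reproduces adjacent-lag correlations near 0.95 and maximum VIFs well
above 10, and lag weights concentrated on the long lags (`lag7`-`lag9`) so
that the distant exposure windows carry the strongest association. The
intercept (20 per 100,000) and noise sd (2 per 100,000) give incidence rates
in the 40-60 range with a clearly dominant exposure signal.

Two independent RNG sub-streams are derived from the single seed, one for
exposures and one for incidence noise, so either can be varied while the
other is held fixed. Exposures are clipped at 1 ug/m3 (a config flag turns
clipping into an error) and incidence at 0; both events are logged.

What the generator does *not* emulate: spatial correlation between regions,
population size and age structure (incidence is modelled directly as a rate),
measurement error in the satellite exposure surface, and any nonlinearity in
the exposure-response. Tests passing on this generator therefore demonstrate
the *mechanics* of each method under realistic collinearity — not that the
methods recover truth on real registry data.

## Association screening

`lag_correlation()` tests each lag column and the incidence series for
normality (Shapiro-Wilk) and uses Pearson's correlation when both p-values
exceed `alpha` (default 0.05), Spearman's rank correlation otherwise.
P-values are two-sided and deliberately uncorrected: the screen is
exploratory, and a multiplicity adjustment would change its meaning.

`grey_relational()` implements Deng's grey relational degree: normalize each
series, form pointwise deviations from the reference,
`xi_i(t) = (Dmin + rho * Dmax) / (D_i(t) + rho * Dmax)` with `Dmin`/`Dmax`
global over all comparisons and points, and average over `t`. Design choices
the grey-system literature leaves open:

- **Resolution coefficient** `rho = 0.5`, the conventional default; it bounds
  every degree below by `rho/(1+rho) = 1/3`.
- **Normalization**: mean normalization (divide by the series mean) by
  default, making degrees invariant to common rescaling; `initial` and
  `minmax` schemes are available as parameters.
- **Grouping** for the per-year table (`grey_relational_table()`): within each
  outcome year the incidence across regions is the reference and each lag
  column a comparison; the pooled "overall" group uses all region-years.

Degenerate inputs are defined rather than left to chance: a comparison
identical to the reference gets degree exactly 1; if *all* series coincide
(`Dmax = 0`) every degree is 1; a zero-mean series under mean normalization
is an error.

## Collinearity diagnostics

`diagnose_collinearity()` reports the Pearson correlation matrix of the ten
lags, VIF and tolerance per lag, and the eigenvalue spectrum with condition
indices. VIFs are computed as the diagonal of the inverse correlation matrix
— algebraically `1/(1 - R2_j)` for predictor `j` regressed on the other nine —
and the test suite cross-checks them against a brute-force per-column
regression oracle. Exactly collinear columns yield `VIF = Inf` with a
`singular` flag instead of an error. The conventional flags are VIF > 10 and
condition index > 30.

Eigenvalues are taken from the 10x10 predictor correlation matrix by default.
An alternative convention augments the design with the intercept column and
scales the 11 columns to unit length before the eigen-decomposition; it is
available via `include_intercept = TRUE`. The correlation-matrix convention
is the default because it involves no arbitrary intercept scaling and its
eigenvalue sum (= 10) makes the trace identity testable.

## The three predictors

**Ridge** (`ridge_fit()`, `ridge_trace()`). Predictors and response are
standardized; `beta(k) = (X'X + kI)^{-1} X'y`; predictions are
back-transformed. Note that `X'X = (n-1) R` on standardized data, so `k` is
on the sample-size-dependent cross-product scale — a given `k` shrinks less
in larger samples. The penalty is a tuning input chosen from the ridge trace:
on training data the standardized MSE is non-decreasing and the coefficient
norm non-increasing in `k`, so one looks for the smallest `k` where the
coefficient paths flatten. The ridge-adjusted VIF
`[(X'X + kI)^{-1} X'X (X'X + kI)^{-1}]_jj (n-1)` reduces exactly to the
ordinary VIF at `k = 0` (a tested identity) and quantifies how much of the
variance inflation the penalty has removed.

**Kernel SVR** (`svr_select()`). Epsilon-insensitive support-vector
regression via `e1071::svm` on standardized inputs, one fit per candidate
kernel (linear, sigmoid, RBF, polynomial). The kernel with minimal in-sample
MSE is selected; ties break by higher R2, then by kernel list order. Default
hyperparameters: cost 1, epsilon 0.1, `gamma = 0.1` (i.e. 1/(10 x unit
feature variance) after standardization), polynomial degree 3 — all exposed.
Since a kernel machine has no native coefficients, per-lag relevance is
measured by permutation importance (`feature_importance()`): the mean MSE
increase over `n_repeats` random permutations of one column, deterministic
given the seed. Permuting a constant column scores exactly 0.

**Feed-forward network** (`network_fit()`). A 10 -> h -> h -> h -> 1
architecture with ReLU hidden activations and a linear output, trained
full-batch with Adam (step size 0.01, 2000 epochs by default) on standardized
data, He-style weight initialization under the given seed. The node count `h`
— the same in all three hidden layers, the simplest reading of a
"three hidden layers, 5-20 nodes" design — is tuned over `node_grid` by MSE
on a 20% hold-out split, then the network is refit on all rows at the
selected `h`. A candidate whose loss goes non-finite is skipped with a
warning rather than aborting the grid. Everything (split, initialization,
training) is deterministic given the seed; run-to-run reproducibility is a
tested contract.

All three models are evaluated in-sample by default. That mirrors how small
region-year panels are typically assessed in this literature, where a
held-out year would leave very little training data; it also means the
reported metrics measure goodness of fit, not out-of-sample skill. The
train/test behaviour can be probed through the network's hold-out machinery
and by fitting on subsets, but the pipeline deliberately reports the
in-sample quantities.

## Combination forecasting

`error_matrix()` stacks the three models' error series and forms
`Omega_ij = mean_t(e_i e_j)`. Omega is intentionally *not* mean-centered:
with raw second moments, `w' Omega w` is exactly the combined in-sample MSE
for any weights summing to 1, which makes the optimality guarantee an
identity rather than an approximation.

`compute_weights()` implements three schemes:

- **standard deviation**: `w_i = (S - S_i) / ((m-1) S)`, `S_i = sqrt(Omega_ii)`;
- **reciprocal variance**: `w_i = Omega_ii^{-1} / sum_j Omega_jj^{-1}`;
- **optimal**: `w = Omega^{-1} 1 / (1' Omega^{-1} 1)`, the closed-form
  minimizer of `w' Omega w` subject to `sum(w) = 1`.

Optimal weights may be negative (the minimizer is unconstrained beyond the
sum); since each unit vector is feasible, the optimal combination can never
have higher in-sample MSE than the best single model — the qualitative
pattern that motivates combining at all, and a tested invariant across seeds.
A `nonnegative` flag restricts the solution to the probability simplex, found
by dense grid search at step 1e-3; the same grid search is the fallback when
Omega is singular and the independent oracle against which the closed form is
verified whenever it lands inside the simplex. Degenerate cases are defined:
identical error series give equal weights by symmetry; a model with zero MSE
receives weight 1 under reciprocal variance, with a warning.

## Evaluation metrics

`metrics()` computes MAE, MSE, MAPE (%) and Theil's U. The U statistic is the
bounded U1 inequality coefficient,
`RMSE / (sqrt(mean(y^2)) + sqrt(mean(yhat^2)))` in [0, 1], rather than the
unbounded U2 ratio: U1's range sits naturally with single-digit-percent MAPE
values, and its upper bound (reached by an all-zero forecast of a positive
series) is a useful calibration point. U2 is available behind
`theil_variant = "u2"`. A zero observation makes MAPE undefined; it is
reported as `NA` with an explicit flag while the other metrics are still
computed.

## The pipeline

`run_pipeline()` sequences association -> collinearity -> ridge trace and
fit, SVR selection and importance, network fit -> ensemble -> metric table,
and writes `report.json` plus tidy CSVs (grey-relational table with one
column per year plus overall; lag correlations; correlation/VIF table;
per-model prediction tables with relative errors; the six-row metric table —
three single models and three combination schemes). One global seed drives
derived sub-streams for generation, network training and permutation
importance, and the configuration hash embedded in the report covers the
analysis parameters (not the output directory), so identical configurations
yield byte-identical reports — a tested contract.

## Numerical choices and problem sizes

- Linear systems are solved with dense `solve()` on 10x10 (ridge) and 3x3
  (ensemble) matrices; no iterative solvers are needed at these sizes.
- Exact-collinearity detection falls back from matrix inversion to per-column
  projections so the offending columns are flagged with infinite VIF.
- Test-suite simulations use panels of 150-500 region-years, 20-50 seeds for
  stochastic properties, and reduced network settings (single or paired node
  grids, 200-1500 epochs) — sizes chosen so the full suite exercises every
  contract in well under a coffee break while leaving the default user-facing
  configuration (node grid 5-20, 2000 epochs) untouched.

## Limitations

- In-sample evaluation overstates predictive skill; treat the metric table as
  a fit comparison between models on equal terms, not a forecast audit.
- The optimal-weighting guarantee is in-sample and can degrade out of sample,
  particularly when Omega is nearly singular (highly correlated model
  errors).
- Grey relational degrees depend on the normalization scheme and rho; only
  Deng's degree is implemented.
- The generator's Gaussian AR(1) exposures cannot represent trends, policy
  breaks or spatially clustered pollution, and the linear incidence model
  cannot represent thresholds or saturation.
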