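---
title: "Methods: predicting reaction rates from proteome abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting reaction rates from proteome abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the modelling assumptions behind them, the numerical choices made
where several defensible options exist, and what the synthetic benchmark does
and does not demonstrate about real data.

## 1. Why enzyme abundance is not a rate proxy

Under first-order kinetics $v = k \cdot e \cdot s$, a reaction's rate tracks
its enzyme concentration $e$ only when the substrate level $s$ and rate
constant $k$ are independently fixed. The package's toy model
(`toy_steady_state()`) captures the simplest violation: two enzymes competing
for one substrate supplied at constant rate $C$. At steady state

$$S_1 = \frac{C}{k_1 e_1 + k_2 e_2}, \qquad v_1 = k_1 e_1 S_1, \qquad
v_2 = k_2 e_2 S_1,$$

so $v_1 + v_2 = C$ identically. If the competitor responds to the same
regulatory signals as the focal enzyme (in the generator: its media response
amplified by `coupling_slope`), $S_1$ falls as $e_1$ rises, and the focal
covariation can be zero or negative — e.g. with $e_2 = e_1^2$ and
$k_1 = k_2$, $v_1 = C/(1 + e_1)$ is strictly decreasing in $e_1$. We use the
closed-form steady state rather than ODE integration: the algebraic solution
is exact, which makes oracle tests (mass conservation to $10^{-12}$, exact
sign reversals) possible.

## 2. The statistical model

For each reaction $j$ the pipeline fits

$$v_j = \beta_{0,j} + \sum_i \beta_{i,j} P_i$$

where $P_i$ are log2-transformed protein abundances. Log2 is used because
protein abundances across growth conditions are approximately log-normally
distributed, so the transform symmetrizes the predictor distributions;
positivity of the expression matrix is therefore a hard input contract (no
pseudocounts — a silent pseudocount would distort every log-scale statistic,
so zero or missing abundances are errors the caller must resolve upstream).

Predictor sets come in three scales:

* **focal** — the single annotated enzyme, only for reactions whose mapping
  is bidirectionally 1:1 (the enzyme maps to exactly one reaction too);
  fitted by OLS.
* **subsystem** — all quantified proteins in the reaction's pathway
  (subsystem), used only when *strictly more than* `min_subsystem_size = 5`
  members are quantified; smaller pathways are skipped with reason
  `SUBSYSTEM_TOO_SMALL` rather than fitted unreliably.
* **proteome** — every quantified protein. A `subsystem_mean` scale
  (one column per subsystem, the mean of member log2 abundances) is also
  available as a coarse-grained alternative.

With far more predictors than conditions, coefficients are regularized and
must not be interpreted mechanistically; the package reports their mean and
standard deviation across cross-validation iterations
(`coefficient_stability()`) precisely so that instability is visible. For
coefficient-magnitude displays the predictors can additionally be z-scored
globally across all conditions (`build_predictors(..., zscore = TRUE)`);
predictive runs never use this mode — they standardize within training folds.

## 3. Penalized estimation

`penlm()` minimizes

$$\frac{1}{2n}\sum_c (y_c - \beta_0 - x_c^\top\beta)^2 +
\lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)$$

with $\alpha = 1$ (lasso) or $\alpha = 0$ (ridge); the intercept is never
penalized. Numerical choices:

* **Standardization.** Columns are centred and scaled to unit variance with
  the *population* (denominator $n$) convention, computed on whatever data
  the fit receives — in cross-validation that is the training fold only, so
  no information leaks from held-out conditions. Coefficients are mapped
  back to the caller's scale. Under this convention the single-predictor
  solutions are exactly $\beta = \rho/(1+\lambda)$ (ridge) and the soft
  threshold $\max(|\rho| - \lambda, 0)\,\mathrm{sign}(\rho)$ (lasso), which
  the tests assert to $10^{-8}$.
* **Constant columns** within a training fold get coefficient 0 silently
  (they carry no information there); a constant *response* is an error that
  callers convert into a skip (`CONSTANT_RESPONSE`).
* **Ridge** is solved exactly through one thin SVD, giving the whole
  $\lambda$ path at negligible extra cost.
* **Lasso** uses cyclic coordinate descent on the Gram form with covariance
  updates, warm starts down the path, and a KKT-guided active set (compiled
  code). Convergence is declared when the largest coefficient change in a
  sweep falls below $10^{-10}$; a cap of 200 sweeps per $\lambda$ bounds the
  work in the degenerate regime ($p > n$ at tiny $\lambda$) where the
  minimizer is not unique and cyclic descent drifts along flat directions.
  Final KKT conditions are re-checked so inactive coordinates cannot be
  silently wrong. Exact zeros are genuine (soft thresholding), so sparsity
  counts use `beta != 0` literally.
* **$\lambda$ path**: 100 log-spaced values from $\lambda_{\max}$ (smallest
  penalty with an all-zero lasso solution) down to
  $10^{-4}\lambda_{\max}$; ridge reuses the same scaffold. This spans the
  OLS-to-null range.
* **Selection rule**: minimum mean inner-CV squared error
  (`lambda.min`, not the 1-SE rule — with as few as ~23 training conditions
  the 1-SE band is wide and overshrinks); ties resolve toward the larger
  (more regularized) $\lambda$. Inner folds default to 10, capped at the
  training-set size, with a seeded random assignment.

## 4. Cross-validation and the cross-validated R²

Outer schemes (`cv_scheme()`): `leave_n_out` (default $n=2$, 100 random
iterations), `leave_media_out` (one fold per media type — an extrapolation
test to an unseen nutrient limitation), `leave_growth_rate_out` (one fold per
distinct dilution rate, grouped by exact value equality since chemostat
designs reuse identical set points across media), and `leave_one_out`.

Per reaction, out-of-fold predictions are pooled **per condition by
arithmetic mean across iterations**, then a single

$$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$$

is computed, with SST the total sum of squares of the observations about
their mean over the pooled condition set. $R^2$ can be negative (residual
variance exceeding total variance is a legitimate outcome for a bad
extrapolation, and is reported as such). An alternative pooling — summing
squared errors over every individual out-of-fold prediction — is reported
alongside as `cv_r2_foldwise`, since with leave-$n$-out iterations the two
conventions genuinely differ and neither is canonical.

The leakage contract is testable and tested: refitting any outer-fold model
after deleting the held-out conditions from all inputs reproduces its
coefficients bit-identically.

## 5. Covariation statistics

* **Spearman** uses average ranks for ties (rate vectors legitimately contain
  exact zeros). It is computed from raw abundances; by monotone invariance
  the value on log-abundances is identical, which the tests assert instead of
  computing twice.
* **Pearson** is reported with and without log2 transform of the abundance
  axis.
* **Mutual information** uses the Kraskov–Stögbauer–Grassberger k-NN
  estimator, variant 1 (max-norm joint neighbourhoods, strict-inequality
  marginal counts), default $k = 3$ — suited to the small-$n$ continuous
  samples here, where histogram estimators would be dominated by binning
  choices. Small negative estimates on independent data are an expected
  property of the estimator; they are clipped to 0 with a `clipped` flag
  (the raw value is kept). Inputs where more than half the points are
  duplicated degrade the neighbour counts and raise a `tie_warning`.
* Zero-variance series yield flags, never fabricated coefficients.

## 6. What the synthetic generator emulates — and what it does not

`generator_config()` defaults encode the benchmark study conditions: 5 media
types (named after limiting nutrients) × 5 dilution rates spanning
0.05–0.35 h⁻¹, 200 proteins, 40 reactions (10 simple-constant, 20
simple-hidden, 10 branched), measurement noise 0.25 on the log2 scale.

Latent condition factors are the dilution rate $g_c$ and the media identity.
True protein abundances follow
$\log_2 e_{ic} = b_i + s_i g_c + m_{i,\mathrm{media}(c)}$ with
$b_i \sim N(0,1)$, $s_i \sim N(0,0.5)$, $m \sim N(0,0.5)$ — log-normal
marginals with media effects dominating growth-rate effects over the
simulated dilution range, as in nutrient-limited chemostats. Rates are exact
functions of the **true** enzyme levels: $v = k e$ (simple-constant),
$v = k e S_{\mathrm{media}}$ with a hidden media-specific substrate level,
log2-sd 1 (simple-hidden), and the branched steady state with supply
$C_c = C_0 (1 + g_c)$ — tying rates to growth without making them collinear
with any single protein. The observed matrix adds i.i.d. $N(0, 0.25)$ noise
on the log2 scale: *measurement* noise, so with noise 0 the focal Spearman of
a simple-constant reaction is exactly +1, and noise attenuates observable
covariation without touching the underlying kinetics. Each motif plus five
bystander proteins (drawn from a shared pool, so subsystems may overlap)
forms one subsystem, clearing the >5 quantified-members rule. Values are
rounded to 12 significant digits at generation so the TSV round trip is
bit-exact. `coupling_slope = 2` (the competitor's media response doubled) is
a free knob, not a claim about biology — the literature does not quantify
how strongly real enzyme pairs are co-regulated.

Deliberately absent: Michaelis–Menten or allosteric kinetics,
post-translational modification, realistic pathway topologies, shared
enzymes across reactions (the generator is 1:1 by construction; the analysis
filters real data to 1:1 anyway), and correlated measurement error. A
passing benchmark therefore shows that the pipeline recovers structure *of
this kind* — condition-driven, low-rank, with distributed rate control — not
that any real proteome-rate dataset will be equally predictable.

## 7. Reporting conventions and degenerate inputs

Quantiles use linear interpolation between order statistics
(`stats::quantile` type 7), so the median of an odd-sized set is the middle
order statistic exactly. Skipped reactions are counted separately from
summarized ones, with structured reasons (`CONSTANT_RESPONSE`,
`SUBSYSTEM_TOO_SMALL`, `NOT_ONE_TO_ONE`); groups with no unskipped results
are omitted with a message. `growth_decoupling()` reports the 5th/95th-style
summary ingredients per reaction so that reactions uncorrelated with growth
but well predicted are visible. Z-scoring uses the sample (n−1) standard
deviation; the choice is absorbed into coefficient scale and does not affect
R².

`run_pipeline()` is deterministic end to end: one user seed is split into
per-stage substreams via a fixed integer map (all below $2^{31}$), RNG state
is saved and restored around every draw, and numeric output is formatted at
12 significant digits — identical configuration and seed give byte-identical
output directories. The manifest records the configuration hash (destination
path excluded), seed and package version.

## 8. Problem sizes used by the tests

The acceptance checks run the full benchmark (25 conditions × 200 proteins,
40 reactions, 100 leave-2-out iterations with nested 10-fold $\lambda$
selection) for the scale-ordering and leakage results; the noiseless
recovery variant uses leave-one-out; the end-to-end byte-identity check uses
a reduced but complete configuration (3 media × 3 rates, 9 reactions, 39
proteins plus competitors, 10 iterations, ridge and lasso) — determinism is
a property of the code path, not of the problem size, and the reduced run
exercises every stage including lasso sparsity reporting. Estimator
tolerances follow from the oracles: closed forms to $10^{-8}$, independent
convex-solver agreement to $10^{-6}$, KSG on a $\rho = 0.9$ Gaussian within
±0.1 of $-\tfrac12\ln(1-\rho^2)$ at $n = 2000$.

## 9. Known limitations

* Rates are inputs; the package does not derive them (no FBA, isotopomer
  balancing, or metabolomics integration).
* Only Gaussian-response linear models with $\alpha \in \{0, 1\}$; no
  elastic-net mixing, no GLM families.
* The sweep cap leaves the lasso slightly suboptimal exactly where the
  solution is non-unique ($p \gg n$, $\lambda \to 0$); the affected path
  tail is essentially never selected by the inner CV.
* Unquantified pathway members are invisible: absence from the expression
  matrix is the only signal, so subsystem membership counts refer to
  quantified proteins.
* Steady-state only: nothing here addresses rates measured out of steady
  state, where any estimate is conditional on an observation timescale.
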