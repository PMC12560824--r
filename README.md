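# proflux

Predicting metabolic reaction rates from proteome abundances.

## The problem

In vivo reaction rates (fluxes) are among the hardest observables in
microbial physiology and environmental microbiology, while the enzymes that
mediate them are comparatively easy to quantify by mass spectrometry or
sequencing. The tempting shortcut — read an enzyme's abundance as a proxy
for its reaction's rate — fails in general. Under first-order kinetics
`v = k·e·s` the rate tracks the enzyme only if the substrate level `s` and
rate constant `k` are independently fixed. In a branched pathway where two
enzymes compete for one shared substrate supplied at rate `C`, the steady
state is

    S1 = C / (k1·e1 + k2·e2),   v1 = k1·e1·S1,   v2 = k2·e2·S1,

so `v1 + v2 = C` exactly, and if `e2` co-varies with `e1` an *increase* in
the focal enzyme can come with a *decrease* in its own reaction rate.

`proflux` turns this observation into a tested analysis pipeline for
steady-state (chemostat) datasets of paired proteomes and reaction rates:

1. **Covariation** — per reaction with a bidirectionally 1:1 annotated
   enzyme: Spearman correlation, Pearson correlation with/without log2
   transform, and Kraskov–Stögbauer–Grassberger (k-NN) mutual information.
2. **Prediction** — per reaction, the linear model
   `v_j = β0_j + Σ_i β_ij · P_i` on log2-transformed abundances `P_i`, with
   predictors at three proteomic scales (the focal enzyme, all quantified
   within-subsystem proteins, the whole proteome), fit by OLS (focal scale)
   or ridge/LASSO with the penalty `λ` chosen by ~10-fold inner
   cross-validation. Outer cross-validation (leave-n-out, leave-media-out,
   leave-growth-rate-out, leave-one-out) yields pooled out-of-fold
   predictions and a cross-validated `R² = 1 − SSE/SST` per reaction.
3. **Reporting** — R² distribution summaries per scale, coefficient
   stability across CV iterations, LASSO sparsity counts, and a check that
   rates need not correlate with growth rate to be predictable.

Because published chemostat datasets cannot be bundled, the package includes
a first-class synthetic-data generator: a factorial media × dilution-rate
design, log-normal condition-driven protein abundances, and reaction rates
that are exact closed-form functions of the true enzyme levels (including
the branched competition motif above). The generator's truth channel makes
every pipeline stage verifiable against known ground truth.

The penalized fits minimize the elastic-net-family objective
`(1/(2n))·Σ(y − β0 − Xβ)² + λ·(α‖β‖₁ + ((1−α)/2)‖β‖₂²)` with internal
predictor standardization (population-sd convention), so single-predictor
closed forms — ridge `β = ρ/(1+λ)`, lasso `β = S(ρ, λ)` — hold exactly and
are enforced in the tests.

## Worked example

```r
library(proflux)

d <- generate_dataset(generator_config(seed = 1))
#> synthetic_dataset: 200 proteins x 25 conditions, 40 reactions

pairs <- extract_focal_pairs(d$rates, d$expression, d$annotations)
ct <- covariation_table(pairs)
ct$summary
#> $n_pairs: 40   $n_flagged: 0
#> $mean_spearman: 0.216   $median_spearman: 0.318

scheme <- cv_scheme("leave_n_out", n_out = 2, iterations = 100, seed = 2)
run <- run_all_scales(d$expression, d$rates, d$design, d$annotations,
                      scheme, seed = 3)
summarize_results(run$results)
#>       scale penalty   cv_scheme n_reactions n_skipped median_cv_r2    q05    q25   q75   q95
#> 1     focal     ols leave_n_out          40         0        0.365 -0.172 -0.041 0.607 0.887
#> 2 subsystem   ridge leave_n_out          40         0        0.647 -0.190  0.388 0.808 0.879
#> 3  proteome   ridge leave_n_out          40         0        0.977  0.450  0.948 0.982 0.987
```

The mean focal Spearman correlation of 0.22 says that across the 40
reactions, knowing only the cognate enzyme's abundance is typically a weak
rate predictor — some reactions even covary negatively with their enzyme
(the branched motifs). The median cross-validated R² rises from 0.37
(single enzyme, OLS) to 0.65 (within-subsystem ridge) to 0.98 (proteome-wide
ridge): rate information is distributed across the proteome rather than
concentrated in the focal enzyme.

Per-reaction detail, including coefficient stability across the 100 CV
iterations:

```r
run$details[["RSH01|subsystem|ridge"]]
#> prediction_result: RSH01, scale=subsystem, penalty=ridge, cv R2 = 0.662 (6 predictors)
head(coefficient_stability(run$details[["RSH01|subsystem|ridge"]]), 3)
#>   predictor_id mean_beta sd_beta frac_nonzero
#> 1        PSH01     0.059   0.012            1
#> 2       PBY027    -0.088   0.016            1
#> 3       PBY072    -0.128   0.014            1
```

A full run (simulate → correlate → predict → report, all outputs as TSV plus
a manifest) is one call:

```r
run_pipeline(list(simulate = list(), predict = list(), seed = 1,
                  out = "out_dir"))
```

`run_pipeline()` also accepts a YAML configuration file; given real data,
replace the `simulate` block with an `inputs` block naming the expression,
rate, condition and annotation files (TSV/GMT, formats documented in
`?read_matrix` and `?read_annotations`).

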