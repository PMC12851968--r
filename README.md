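# cardiosig

Cardiac autonomic signatures from exercise R-R interval dynamics.

`cardiosig` is an R package for researchers studying autonomic nervous
system function through heart rate variability during exercise. It
models beat-to-beat R-R interval (RRi) recordings acquired across a
rest-exercise-recovery protocol (such as a Two-Minute Step Test in
older adults), extracts each subject's **cardiac autonomic signature**
(CAS) — a seven-parameter description of the RRi trajectory — and
relates those signatures to immune-cell predictors (total lymphocytes,
total B cells, and the four CD21/CD11c-defined B-cell subsets) through
Bayesian multivariate regression.

## The model

Each observed interval is Gaussian noise around a coupled-logistic
trajectory:

    RRi_j ~ N( f(t_j | θ), σ² )

    f(t) = α − β·S(t; λ, τ) + c·β·S(t; φ, τ+δ),
    S(t; r, t0) = 1 / (1 + exp(−r·(t − t0)))

with θ = (α, β, c, λ, φ, τ, δ): resting baseline α (ms),
exercise-induced drop β (ms), recovered proportion c, drop and recovery
steepness λ, φ (min⁻¹), drop onset τ (min) and recovery lag δ (min).
The analysis is two-stage: per-subject point estimation of θ by
box-constrained quasi-Newton minimisation of a Huber loss (after
zero-phase Butterworth smoothing and local-regression/MAD ectopic-beat
rejection), then regression of the standardized θ̂ components on
standardized immune predictors — optionally adjusted for age, sex,
body-fat % and muscle mass — with Normal(0, 3) coefficient priors,
sampled by MCMC (5 chains × 2,000 warm-up + 2,000 sampling iterations).
Coefficients are reported in the SEXIT style: posterior median, 95%
highest-density interval, probability of direction (pd), and posterior
mass outside a ±0.1 SD region of practical equivalence (ps).

A synthetic-data module generates single trajectories and full cohorts
(immune marginals matched to a reference older-adult cohort) with known
ground truth, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(cardiosig)

# simulate a 30-subject cohort with a known immune-autonomic effect:
# +0.48 SD of baseline RRi per SD of CD21+CD11c+ B-cell count
coh <- simulate_cohort(30, effects = list(alpha = c(cd21p_cd11cp = 0.48)),
                       seed = 1)

# run the full two-stage pipeline
res <- run_pipeline(coh$recordings, coh$immune,
                    pipeline_config(spec = regression_spec(seed = 1)))
cas_report(res)
```

The report prints the cohort-level CAS table and the SEXIT effect table
(output from this exact run):

```
Cohort CAS parameters (mean [95% CI]):
  alpha    881.234 [  873.029,   889.438]
  beta     410.715 [  400.462,   420.968]
  c          0.900 [    0.892,     0.909]
  lam        2.902 [    2.785,     3.018]
  phi        2.189 [    2.085,     2.294]
  tau        6.866 [    6.824,     6.907]
  delta      2.489 [    2.440,     2.537]

SEXIT summary (standardized effects):
  alpha:lymphocytes            ES   0.06 [ -0.21,   0.33]  pd  69.2%  ps  50.0%
  alpha:b_total                ES  -0.19 [ -0.50,   0.12]  pd  89.4%  ps  75.2%
  alpha:cd21p_cd11cp           ES   0.63 [  0.38,   0.91]  pd 100.0%  ps 100.0%
  ...
```

Reading the output: the cohort means reproduce the generator's
signature (baseline ≈ 885 ms, drop ≈ 404 ms, 89% recovery), and the
planted CD21⁺CD11c⁺ effect on baseline RRi is detected decisively —
posterior median 0.63 (at n = 30 the sample correlation between one
predictor and the response wanders this far from 0.48), probability of
direction 100% and all posterior mass outside the ±0.1 ROPE — while
predictors without planted effects show small medians and unremarkable
pd/ps.

Individual stages are available as plain functions — `simulate_rri()`,
`inject_ectopics()`, `preprocess_rri()`, `fit_cas()`,
`fit_cas_regression()`, `sexit_summary()`, `mcmc_diagnostics()` — and
all tables read/write CSV so each stage can be rerun in isolation. See
`vignettes/cardiosig-methods.Rmd` for the modelling details and design
choices.

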