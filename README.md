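# biosimpk

Population pharmacokinetics (popPK) of subcutaneously administered
TNF-inhibitor biosimilars — adalimumab (40 mg q14d) and etanercept
(50 mg q7d) — for pharmacometricians and clinical pharmacologists working
with sparse therapeutic-drug-monitoring data in rheumatoid arthritis.

The package implements the full analysis pipeline around a one-compartment
first-order-absorption model:

* **Structural kinetics** — closed-form one- and two-compartment solutions
  with multiple-dose superposition and analytic steady-state metrics. For a
  dose *D* into a depot, the one-compartment concentration is the Bateman
  function *C(t) = D·ka/(V_D(ka−ke))·(e^(−ke·t) − e^(−ka·t))* with
  *ke = CL/V_D*; CL and V_D are apparent (bioavailability-confounded)
  values.
* **Hierarchical model** — lognormal between-subject variability
  (*P_i = θ·g(cov_i)·e^(η_i)*, *η_i ~ N(0, Ω)*), power/proportional-shift
  covariate effects (age, body weight, sex, concurrent csDMARD), and
  additive/proportional/combined residual error
  (*Var(y|f) = f²σ_prop² + σ_add²*).
* **Estimation** — deterministic maximum marginal likelihood (adaptive
  Gauss–Hermite quadrature at the per-subject conditional modes), observed
  Fisher-information standard errors, AIC and likelihood-ratio model
  comparison, and a covariate-selection scan.
* **Diagnostics** — PRED/IPRED, IWRES, Monte-Carlo PWRES and NPDE with
  Shapiro–Wilk normality testing.
* **Synthetic data** — a generator emulating the study's trough-oriented
  sparse sampling designs and cohort covariates, plus a NONMEM-style CSV
  reader/writer.
* **Regimen simulation** — virtual-population percentile bands and
  typical-individual comparison of alternative dosing intervals against
  therapeutic windows (adalimumab 5–8 mg/L, etanercept 2.1–4.7 mg/L).

Built-in models `model_adalimumab()` and `model_etanercept()` carry the
published final parameter estimates (e.g. etanercept: CL 0.0404 L/h,
V_D 7.76 L, ka fixed at 0.0396 /h).

## Worked example

```r
library(biosimpk)

# alternative etanercept dosing intervals for the typical patient
compare_regimens(model_etanercept(),
                 list(dosing_regimen(50, 120),   # q5d
                      dosing_regimen(50, 168),   # q7d (licensed)
                      dosing_regimen(50, 240)),  # q10d
                 therapeutic_window(2.1, 4.7))
#>   dose_mg interval_h     C_avg C_trough_ss  C_max_ss C_at_horizon
#> 1      50        120 10.313531    8.484503 11.441135     9.519544
#> 2      50        168  7.366808    5.296972  8.819681     5.296825
#> 3      50        240  5.156766    2.980555  6.992374     6.143265
#>   accumulation_ratio time_to_90pct_ss_h window_position
#> 1           2.152386                480           above
#> 2           1.715303                504           above
#> 3           1.401841                480          within
```

The licensed 50 mg q7d regimen gives a typical steady-state trough of
5.30 mg/L — above the 2.1–4.7 mg/L window, matching the study's finding —
while stretching the interval to 10 days brings the trough inside the
window with a similar time to steady state (480 vs 504 h to reach 90% of
the asymptotic trough).

A round trip through the synthetic-data generator and the estimator:

```r
m  <- model_etanercept()
ds <- generate_dataset(m, builtin_design("etanercept"),
                       dosing_regimen(50, 168), n_subjects = 6,
                       n_dropout = 2, seed = 1)
ds
#> Study dataset: 6 subjects, 78 dose events, 40 observations (34 in likelihood)

fit <- fit_poppk(ds, m)           # sparse n=6 fit; wide RSEs expected
diagnostics_table(fit, seed = 1)  # PRED/IPRED/IWRES/PWRES/NPDE + SW verdict
```

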