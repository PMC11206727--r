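---
title: "Population PK of adalimumab and etanercept biosimilars: models, estimation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of adalimumab and etanercept biosimilars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosimpk)
```

## The problem

Adalimumab and etanercept are TNF-inhibitor biologics self-administered
subcutaneously by rheumatoid-arthritis patients at fixed licensed regimens
(40 mg every 14 days and 50 mg every 7 days, respectively). Circulating drug
levels vary widely between patients and are associated with treatment
response, which motivates therapeutic drug monitoring and the question this
package is built around: can the dosing interval be altered while keeping a
typical patient's trough concentration inside a proposed therapeutic window
(5–8 mg/L for adalimumab, 2.1–4.7 mg/L for etanercept)?

Clinical sampling in this setting is sparse — a handful of trough samples per
patient over 12 weeks — so individual PK analysis is impossible and a
population (hierarchical, nonlinear mixed-effects) approach is required.

## The model

**Structural model.** A one-compartment model with first-order subcutaneous
absorption and first-order elimination, parameterised as apparent clearance
CL (L/h) and apparent central volume V_D (L) (apparent because
bioavailability F is confounded with both after extravascular dosing; no
explicit F is carried). The single-dose solution is the Bateman function

$$C(t) = \frac{D\,k_a}{V_D\,(k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right),
\qquad k_e = CL/V_D,$$

with the limit $C(t) = D\,k_a\,t\,e^{-k_a t}/V_D$ as $k_a \to k_e$; the
degeneracy switch uses a relative threshold of $10^{-8}$ on $|k_a-k_e|/k_e$
because the generic formula loses precision to cancellation there. Multiple
dosing uses superposition at nominal dose times, and steady-state quantities
come from geometric accumulation of each exponential term
($1/(1-e^{-\lambda\tau})$ per term) rather than long simulation — exact and
fast. A two-compartment extension (intercompartmental clearance Q,
peripheral volume V_P) is provided for structural model comparison; both
closed forms are validated against ODE integration to relative error below
$10^{-6}$ in the test suite. Time is in hours, doses in mg, concentrations
in mg/L throughout.

**Between-subject variability.** Lognormal ("exponential") random effects:
$P_i = \theta\,g(cov_i)\,e^{\eta_i}$, $\eta_i \sim N(0, \Omega)$. The
log-scale SD $\omega$ relates to the lognormal CV by
$CV = \sqrt{e^{\omega^2}-1}$ (`cv_to_omega()` / `omega_to_cv()`).

**Covariate model.** Continuous covariates (age, body weight) enter as power
terms centred on the population median, $(x/x_{med})^\beta$; binary
covariates (sex, concurrent csDMARD) as proportional shifts $e^{\beta x}$.
These functional forms are a package choice following pharmacometric
convention (they keep parameters positive); the source analysis does not
state the forms it screened.

**Residual error.** Combined additive + proportional:
$y = f(1+\varepsilon_p) + \varepsilon_a$, so
$\mathrm{Var}(y\mid f) = f^2\sigma_{prop}^2 + \sigma_{add}^2$. Simulated
measurements may be negative through the additive term; they are retained
for estimation fidelity and clipped at zero only for display.

## Built-in study models

`model_adalimumab()` and `model_etanercept()` carry the published final
estimates. Three reported values are ambiguous in their printed units and
are interpreted as follows (all overridable through constructor arguments):

* Adalimumab $\omega$ values printed as CV% (68.9 on CL, 15.6 on V_D) are
  lognormal CV%, converted internally to log-scale SDs.
* Etanercept $\omega_{CL} = 0.173$ printed under a "(%)" header is read as
  the log-scale SD itself (≈17.3% CV); a CV of 0.173% would be implausible
  for sparse clinical data.
* Etanercept $\sigma_{prop}$ printed as 0.46 (%) is read as the fraction
  0.46 (46%), for the same reason.

The adalimumab absorption rate constant is fixed at 0.01167 /h following the
text of the source analysis and the prior model it cites, although its
parameter table prints 0.1167 /h; the constructor argument `ka` lets users
adopt the other reading. Both models keep `ka` fixed (no BSV), mirroring the
published model-building decisions; the etanercept model additionally fixes
$\sigma_{add} = 10^{-4}$ mg/L (a stability device, effectively
proportional-only error).

A model can be written to and recovered from a YAML config mirroring the
parameter tables (`write_model_config()` / `read_model_config()`).

## The synthetic-data generator

The study's raw concentrations are available only on request, so the
package generates study-like cohorts. `builtin_design()` reproduces the two
sampling schedules: baseline (pre-treatment), 1 h post-first dose, then
pre-dose troughs at 2, 4, 6 and 12 weeks, with an extra day-6 sample in the
etanercept arm. Covariates are drawn from lognormal age/weight
distributions matched to the reported cohort medians and IQRs (weight
85.5 kg [66–111] adalimumab, 70.5 kg [69–84] etanercept) and Bernoulli
sex/csDMARD indicators at the reported frequencies. A uniform-random,
seed-controlled dropout option reproduces the published sample counts
(58 of 60 scheduled adalimumab samples, 40 of 42 etanercept); which samples
were actually missing is not reported, so placement is random.

Baseline samples are drug-naive: true concentration zero, recorded with
`mdv = 1` and excluded from the likelihood by default (they carry no PK
information). No lower limit of quantification is applied, as none is
reported. Datasets round-trip through a NONMEM-style CSV dialect (columns
`ID, TIME, AMT, DV, EVID, MDV, AGE, WT, SEX, CSDMARD`; at a shared nominal
time the observation row precedes the dose row, encoding true troughs).

What the generator does *not* emulate: assay-plate structure, triplicate
measurement and calibration; anti-drug antibodies; dosing-time deviations
(nominal times are used, as in the source analysis); time-varying
covariates. Passing tests therefore demonstrate correctness of the
machinery under the stated hierarchical model, not robustness to these
real-data features.

## Estimation

`fit_poppk()` maximises the marginal likelihood with the random effects
integrated out per subject by adaptive Gauss–Hermite quadrature centred on
the conditional mode (9 nodes for one random-effect dimension, 5 per
dimension for two; one node gives the Laplace approximation, used beyond
two dimensions). The estimator is deterministic — no simulation enters the
objective — which makes fits exactly reproducible and invariant to subject
ordering. A stochastic EM (SAEM-type) scheme would be the other standard
choice here; the deterministic approximation was preferred because the
estimation contract (maximised marginal likelihood, honoured fixed flags,
iteration cap) is algorithm-agnostic, and the quadrature agreement with a
31-node oracle is verified directly in the test suite (to within 0.1 in
−2LL on a toy problem).

Numerical choices worth knowing:

* Structural parameters, $\omega$ and $\sigma$ values are estimated on the
  log scale (positivity); covariate coefficients are unconstrained.
* The inner mode search is a safeguarded Newton iteration vectorised across
  subjects with warm starts between outer iterations, per-subject step
  halving, and a per-subject quasi-Newton fallback (started from both the
  current iterate and the origin) for subjects whose inner gradient has not
  vanished.
* The curvature used for the Laplace/adaptive scaling is recomputed at the
  mode with a second-difference step of $8\times10^{-3}$: smaller steps
  carry enough roundoff from cancellation (~$10^{-5}$ relative) to corrupt
  the outer finite-difference gradients.
* The outer optimiser is `nlminb` with an explicit central-difference
  gradient (step $10^{-4}$) and a 500-iteration cap; convergence is taken
  from the optimiser's own criterion, and a fit that exhausts the cap or
  reports failure is returned flagged rather than discarded.
* Parameters named in `fixed` never enter the optimisation and are returned
  bit-identical, with no SE/RSE entries.

Standard errors come from the observed Fisher information (numerical
Hessian of the marginal log-likelihood at the optimum) propagated to the
natural scale by the delta method; RSE% is $100\cdot SE/|\hat\theta|$. The
published table footnote prints the inverted ratio; the universal
definition is used here. Model comparison uses AIC
($-2LL + 2p$) and, for nested models (checked by estimated-parameter-set
inclusion), the likelihood-ratio $\chi^2$ test. `covariate_scan()` fits one
candidate effect at a time (age, weight, sex, csDMARD on CL and V_D by
default) and selects the lowest-AIC candidate among those with LRT
$p < 0.05$, treating an AIC improvement of less than 2 as a tie resolved in
favour of the simpler model. Random-effect correlations can be supplied
(`bsv_corr`) but default to none; the source analysis reports testing
correlations without retaining any.

## Diagnostics

`diagnostics_table()` assembles PRED/IPRED (typical and empirical-Bayes
predictions), IWRES, PWRES and NPDE. PWRES and NPDE are computed by
Monte-Carlo simulation from the population model rather than first-order
linearisation — exact under the nonlinear model at negligible cost at this
scale (default 1000 replicates; the source analysis does not state its
replicate count). NPDE decorrelates each subject's observed and simulated
vectors with the Cholesky factor of the empirical simulation covariance
(with a $10^{-10}$ diagonal jitter for the near-singular covariances sparse
designs produce) and uses the $(\mathrm{rank}+0.5)/(n_{sim}+1)$ convention,
which keeps every pde strictly inside (0,1) and every NPDE finite.
Normality is tested with Shapiro–Wilk at $\alpha = 0.05$. Under the true
model the suite verifies IWRES/PWRES mean within ±0.1 and SD within
0.9–1.1, and a null Shapiro–Wilk rejection rate between 2% and 10% over 200
replicates; a deliberately misspecified model (halved clearance) is
rejected in well over half of replicates at 16 subjects × 7 samples.

## Regimen simulation

`simulate_population_profile()` draws a virtual population (default 10,000
individuals, hourly grid, percentiles by direct order statistics) and
returns median/5th/95th percentile bands, which reflect BSV only unless
`include_residual = TRUE` adds assay noise — trajectory bands are the
default because that is what concentration-profile figures depict.
`compare_regimens()` evaluates the typical individual deterministically.
One subtlety is deliberate: the adalimumab model implies an effective
half-life of V_D/CL ≈ 94 days, so the 12-week study window is far from
steady state. Window position is therefore judged on the *analytic*
steady-state trough, with the finite-horizon concentration reported
separately; the package reports both and does not adjudicate between the
published window statements and the printed parameters (whose steady-state
average, ≈42 mg/L, lies far above the 5–8 mg/L window). Time to steady
state is defined as the first trough reaching 90% of its asymptote, a
definition the package labels explicitly since "time to steady state" is
otherwise ambiguous.

```{r regimens}
compare_regimens(model_etanercept(),
                 list(dosing_regimen(50, 120), dosing_regimen(50, 168),
                      dosing_regimen(50, 240)),
                 therapeutic_window(2.1, 4.7))
```

## Simulation protocols and problem sizes

The parameter-recovery protocol used by the tests and the acceptance script
generates 200 subjects per arm under the published values and refits them.
Each subject gets a rich 12-sample schedule (`design_recovery()`): for
etanercept, absorption-phase and trough samples across the 12-week window;
for adalimumab, six pairs of troughs 24 h apart between weeks 16 and 48.
The adalimumab choices follow from its kinetics — early samples are nearly
uninformative at these noise levels ($\sigma_{add} = 10.8$ mg/L), late
troughs carry most of the between-subject signal, and near-replicate pairs
(the profile is essentially flat over 24 h at a 94-day half-life) separate
residual error from BSV, which is otherwise the dominant confounding in
recovering $\omega_{CL}$. Even so, the maximum-likelihood estimate of a
single variance component from 200 subjects at these noise levels retains
sampling spread of several CV points; the recovery tolerance (15% relative
on the CV) reflects that.

Operating-characteristic simulations run at reduced scale: covariate-scan
null behaviour over 30 replicates of 40 subjects and power over 10
replicates of 100 subjects; NPDE null calibration over 200 replicates of
the 16-subject study-sized design.

## Limitations

* Three-compartment and nonlinear (target-mediated) elimination models, IV
  routes, inter-occasion variability and anti-drug-antibody effects are out
  of scope.
* The Laplace/AGQ estimator shares the usual small-sample caveats of
  marginal ML: variance components are noisy at 10–16 subjects (as the
  published RSEs themselves show), and BSV on weakly identified parameters
  may collapse.
* The generator's covariate distributions are moment-matched to published
  summaries, not resampled patients.
* The covariate scan controls each likelihood-ratio test at
  $\alpha = 0.05$, not the family-wise rate across its eight default
  candidates; with calibrated tests the chance of selecting some spurious
  effect on null data is therefore in the 20–30% range (the test suite
  measures it), and users wanting family-wise control should tighten
  `alpha` or widen `aic_tie` accordingly.
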