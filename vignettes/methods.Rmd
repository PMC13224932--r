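---
title: "Models and simulation methods in lutadosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation methods in lutadosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutadosim)
```

`lutadosim` implements a population pharmacokinetic (popPK) and
exposure–dosimetry analysis pipeline for Lu-177 DOTATATE radioligand therapy:
the individual and population PK models, the empirical kidney and bone-marrow
dosimetry regressions, and the Monte Carlo virtual-subject and virtual-trial
engines used to evaluate threshold-exceedance risk under flat dosing
(7.4 GBq per cycle, 4 cycles every 8 weeks). Because the underlying clinical
datasets are not public, a synthetic-data module generates cohorts and
datasets with the same statistical structure and known ground truth, so every
fitting routine in the package is exercised as a checkable recovery
experiment.

## The individual PK model

Disposition is a two-compartment linear model with zero-order (constant-rate
infusion) input into, and first-order elimination from, the central
compartment. It is parameterized by macro constants — clearance $CL$ (L/h),
central volume $V_c$ (L), intercompartmental clearance $Q$ (L/h) and
peripheral volume $V_p$ (L) — matching how the estimates are reported.
With micro constants $k_{10} = CL/V_c$, $k_{12} = Q/V_c$, $k_{21} = Q/V_p$,
the disposition exponents $\lambda_{1,2}$ are the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$. For an
infusion at rate $R$ the central concentration is the biexponential

$$C(t) = \frac{R}{V_c}\left[A\,(1-e^{-\lambda_1 t}) +
B\,(1-e^{-\lambda_2 t})\right],\qquad
A = \frac{k_{21}-\lambda_1}{\lambda_1(\lambda_2-\lambda_1)},\;
B = \frac{k_{21}-\lambda_2}{\lambda_2(\lambda_1-\lambda_2)},$$

with $A + B = 1/k_{10}$ so that $C(\infty) = R/CL$. Profiles for arbitrary
dose histories are linear superpositions of such step responses switched on
at the infusion start and off at its end (inclusive–exclusive in time);
overlapping infusions simply add rates. Repeated eigenvalues
($\lambda_1=\lambda_2$) are a measure-zero degenerate set and are rejected
rather than handled by a limiting form. The closed form is verified in the
test suite against numerical ODE integration to $10^{-6}$ relative accuracy
over the six decades of dynamic range above $10^{-6}\times C_{max}$; below
that level double-precision round-off in any method exceeds the tolerance,
so the comparison is not meaningful.

Exposure metrics use the standard non-compartmental conventions:
`auc_last` by the linear-up/log-down trapezoid (logarithmic interpolation on
declining segments, which is near-exact on exponential decay and keeps sparse
clinical schedules accurate to well under 1%; the plain linear trapezoid is
available via `auc_method = "linear"`), `auc_inf` by terminal-slope
extrapolation $C_{last}/\lambda_z$ with $\lambda_z$ from a log-linear
regression on the tail of the grid, and `cmax`/`tmax` read off the grid. A
flat or rising terminal phase raises a diagnostic error rather than returning
a misleading extrapolation.

## Units and the amount scale

Kinetics are linear, so the unit of "amount" is a single multiplicative
convention, exposed as `amount_scale` (amount units per GBq of administered
activity). The package default carries doses in MBq (`amount_scale = 1000`),
so concentrations are activity-equivalent blood concentrations in MBq/L: a
7.4 GBq infusion into a ~20 L central volume peaks near 340 MBq/L and the
terminal phase at one week is still a few MBq/L. This choice makes the
reported additive residual SD of 0.40 a genuinely *low* error across the
measured profile, consistent with the precision at which the disposition
parameters (including $V_p$) were reported; under a microgram-mass
convention the same profile would fall below 0.40 within hours and the
peripheral compartment would be practically unidentifiable. Any other unit is
a rescaling of this single constant.

## The population model and its estimation

Inter-individual variability (IIV) is log-normal on $CL$ and $V_c$:
$CL_i = CL\,e^{\eta_{CL,i}}$, $V_{c,i} = V_c\,e^{\eta_{Vc,i}}$ with
$(\eta_{CL}, \eta_{Vc}) \sim N(0, \Omega)$, $\Omega$ built from SDs
$(\omega_{CL}, \omega_{Vc})$ and correlation $\rho$. The adult model uses the
full 2x2 $\Omega$ (defaults: $\omega_{CL} = 0.41$, $\omega_{Vc} = 0.52$,
$\rho = 0.70$); the adolescent structure fixes $\omega_{Vc} = 0$ and drops
$\rho$ (`vc_iiv = FALSE`). Log-normal IIV guarantees positive individual
parameters.

Residual error is additive Gaussian with SD $\sigma$ on the concentration
scale, *truncated at zero*: concentrations cannot be negative, so the
simulator resamples negative draws and the likelihood uses the matching
zero-truncated density (each observation contributes an extra
$\log\Phi(\hat{y}/\sigma)$ normalizer). Fitting the untruncated Gaussian to
data whose late samples sit at the noise floor biases clearance downward and
inflates the IIV, so simulator and estimator deliberately share one residual
model. An additive-on-log-scale alternative is available at simulation time
(`residual = "log_additive"`) for sensitivity analyses, reflecting that the
scale of the reported "constant residual error" is not fully specified.

Estimation maximizes the marginal likelihood with the Laplace approximation:
per subject, the conditional mode of $\eta$ is found by damped Gauss–Newton
on the penalized least-squares objective and the log-determinant of the
conditional Hessian is evaluated by central finite differences (falling back
to the always-positive-definite Gauss–Newton surrogate if the numerical
Hessian is indefinite). This layer is compiled (Rcpp) because the
parameter-recovery studies refit hundreds of simulated trials. The outer
problem runs on transformed parameters (logs for positive quantities,
$\mathrm{atanh}$ for $\rho$, a Cholesky-free 2x2 covariance that is positive
semidefinite by construction) through `stats::nlminb`; when the PORT
algorithm reports false convergence on a stiff ridge, simplex and
quasi-Newton rounds alternate until progress stops. Starting values default
to a naive two-stage estimate — per-subject curve fits summarized by medians
and MAD-type spreads, robust to subjects whose late samples are pure noise.
`n_restarts` controls multistart (default 3): the first start is the
initializer, the second pins the IIV SDs at their lower bound (this
deterministic start escapes the classic ridge where inflated random effects
absorb a fixed-effect offset, and is what makes noise-free degenerate
datasets recover exactly), and further starts jitter the initial
log-parameters; the best final $-2\log L$ wins. Standard errors come from
the inverse observed Fisher information (numerical Hessian of the negative
log-likelihood on the natural scale), reported as %RSE = SE/estimate × 100.
The test suite checks the Laplace $-2\log L$ against adaptive Gauss–Hermite
quadrature (9 nodes per dimension, ODE-based predictions) to within 0.5
units.

Empirical Bayes estimates (EBEs) are the conditional modes of $\eta$ given a
subject's data; they shrink to zero as $\omega \to 0$ or as $\sigma$ grows.
Covariate screening correlates EBEs with baseline covariates (Spearman rank
correlation with its test p-value, candidates flagged at a configurable
$\alpha = 0.05$); the reference analyses found no covariate effects, and on
data generated without covariate dependence the flag rate equals $\alpha$ by
construction. Full covariate model building is out of scope.

The prediction-corrected VPC bins observations in time (by default at the
shared sampling times), scales each record by the ratio of the bin-median
population prediction to its own population prediction, and compares the
observed bin medians with the 5th–95th percentile band of bin medians from
`n_sim` simulated replicates. A record with zero population prediction (a
pre-dose sample) is left uncorrected. Because the observed median is
exchangeable with the simulated medians when the model is true, the expected
band coverage is essentially the nominal 90%; self-consistency tests
therefore assert mean coverage of at least $0.90 - 3\,\mathrm{SE}$ over the
simulated bins rather than a bare 0.90, which a fair coin of that exact
probability would fail half the time.

## Exposure–dosimetry models

With one dosimetry value per subject per organ, the kidney and bone-marrow
models are independent nonlinear regressions on administered activity (the
exposure surrogate) and creatinine clearance (CrCL), normalized at the adult
reference point of 7.4 GBq and 99 mL/min:

$$\text{kidney (Gy/cycle)} = A_{pop}
\left(\tfrac{\text{activity}}{7.4}\right)^{B_{pop}}
\left(\tfrac{\text{CrCL}}{99}\right)^{C_{pop} + \beta_{study}\cdot
\mathbb{1}[\text{adolescent}]},\qquad
\text{marrow} = D_{pop}
\left(\tfrac{\text{activity}}{7.4}\right)^{E_{pop}}
\left(\tfrac{\text{CrCL}}{99}\right)^{F_{pop}}.$$

`dosimetry_params_adult()` carries the adult estimates
($A_{pop} = 4.3$, $B_{pop} = 0.66$, $C_{pop} = -0.552$; $D_{pop} = 0.246$,
$E_{pop} = 0.597$, $F_{pop} = -1.11$; proportional residual SDs $b_1 = 0.515$,
$b_2 = 0.675$) and `dosimetry_params_pooled()` the pooled adult + adolescent
estimates ($A_{pop} = 4.37$, $\beta_{study} = +1.58$ on the kidney CrCL
exponent, so adolescent kidney dose *increases* with CrCL; marrow unchanged
in form). Cumulative dose over up to four cycles is the sum of per-cycle
predictions at fixed covariates.

Residual error is proportional: observed = predicted × (1 + bε) with
ε ~ N(0,1) and negative factors resampled (truncation at zero — a dose cannot
be negative). The likelihood uses the matching truncated density; its
normalizer $\Phi(1/b)$ is constant across records, and including it removes
the upward bias in the baselines that the naive proportional-Gaussian
likelihood shows against truncated data. One residual draw is made per
subject per organ and carried through cumulative sums — the residual
represents between-subject unexplained variability, since the design has one
dosimetry value per subject. A matched-CV, median-preserving log-normal
residual (`residual = "lognormal"`) is available by configuration. Positive
parameters ($A_{pop}$, $D_{pop}$, $b_1$, $b_2$) are optimized on the log
scale; exponents are unconstrained. Model comparison uses
BIC = $-2\log L + k\log n$ per organ; the study-effect kidney model is
selected when it lowers the kidney BIC. Identifiability of the activity
exponents requires activity to vary across subjects, so the synthetic
recovery designs draw per-subject activities from standard dose-escalation
levels (1.85/3.7/5.55/7.4 GBq); with a single activity level the exponent
stays at its initializer and the remaining parameters are unaffected.

The dosimetry VPC simulates the observed design `n_sim` times (default 500)
and reports the observed bin medians against the 5th/50th/95th percentile
bands of the simulated bin medians, binned separately against CrCL and
against activity.

## Monte Carlo engines

**Scenario grid.** Eight activities (1–8 GBq) by thirty CrCL values
(35–180 mL/min in steps of 5) give the 240 scenarios; each cell simulates
500 virtual subjects at fixed covariates over 4 cycles, with one proportional
residual draw per subject applied to the cumulative dose, and reports the
median dose and per-threshold exceedance fractions (kidney 23/29 Gy, marrow
2 Gy). The step size of the CrCL grid is the one free choice and is
configurable. Noise can be switched off (`noise = FALSE`), in which case the
cell median is the deterministic prediction — both readings of "median
dosimetry from virtual subjects" are supported. The simulated exceedance is
verified against the analytic truncated-normal tail probability. Note one
knife-edge consequence of the truncated residual: its median factor is
slightly above 1 (≈1.059 at $b_2 = 0.675$), so at exactly CrCL = 55 the noisy
median marrow dose sits on the 2 Gy line while the deterministic prediction
is 1.89 Gy; the safety statement that thresholds are respected is therefore
asserted *above* 55 mL/min, matching "greater than 55".

**Virtual trials.** A pool of `n_per_trial x n_trials` subjects (2,500 or
5,000 for trials of 5 or 10) draws CrCL from a truncated normal. The
published simulation used an external pediatric CrCL distribution whose
parameters are not printed; the default stand-in matches the adolescent
cohort summary (center 122 mL/min, bounds 86–160, SD = range/5 so the bounds
sit at ±2.5 SD) and is fully configurable so the published distribution can
be plugged in. The pool is partitioned into sequential trials (equivalent in
distribution to independent trials); each trial's median (even sizes: mean of
the two middle order statistics) is compared with the kidney thresholds, and
the fraction of trials whose median exceeds each threshold is reported along
with the trial-median distribution. Because the published distribution
parameters are unavailable, the package asserts the qualitative conclusion —
exceedance probabilities below the predefined 20% limit for both trial sizes
— rather than the paper-reported percentages.

**Cohort exceedance summaries.** For each population, 500 trials of 500
virtual subjects bootstrap covariates from the cohort table; the per-trial
fraction exceeding each threshold after 4 cycles is summarized by its median
and 5th/95th percentiles.

**Flat dosing.** Cumulative doses are stratified by configurable body-weight
bins (and population); under flat dosing the strata should overlap, and on
synthetic data without weight dependence the rank correlation between bin
index and bin median is non-significant in the expected fraction of
replicates. Weight is generated but deliberately inert in every model.

## Synthetic data

Cohort covariates (age, weight, BSA, CrCL, kidney mass) are truncated
normals centred at the reported medians with the reported ranges as hard
bounds and SD = range/5; only medians and ranges are published, so this is
the minimal distributional assumption consistent with them. Covariates are
drawn independently (the true joint structure is unknown); sex is Bernoulli
with the reported proportions and is used by nothing downstream. Defaults:
47 adults, 11 adolescents (10 in the pooled dosimetry design of 57 subjects
/ 114 records). The default PK design is 4 cycles of 7.4 GBq every 1,344 h
infused over 0.5 h, sampled at 0.25, 0.5, 1, 2, 4, 8, 12, 24, 48, 96, 168
and 1,176 h — 12 samples spanning the infusion peak, the distribution knee
and the terminal phase; the true schedules are unpublished. Generators are
deterministic under a single master seed (`set.seed` at entry, subjects in
fixed order) and embed their ground truth as attributes.

What the synthetic data do *not* emulate: assay quantification limits and
BLQ handling, between-occasion variability across cycles, covariate
correlations (e.g. weight–CrCL), imaging-based dosimetry error structure,
and dropout. Passing recovery tests therefore demonstrates that the
estimators are consistent and the pipeline is internally coherent under the
stated models — not that the models are correct for any particular real
dataset.

## Problem sizes and numerical choices

The shipped studies use desk-scale sizes chosen to give stable Monte Carlo
summaries: 100 replicate popPK fits of 20 subjects x 12 samples for the
PK recovery study, 200 replicate dosimetry fits of 47 (or 57 pooled)
subjects, 500 virtual subjects per scenario cell, 500 trials per design, and
500-simulation VPCs. Inner Gauss–Newton iterations stop at a step norm of
1e-9 or a relative gradient of 1e-7; the outer optimizer is bounded 6 log
units around its start with IIV SDs in [1e-4, 5] and |atanh ρ| ≤ 3. Ties in
quantile-based binning merge under-filled bins into their left neighbour.
Monte Carlo assertions use 3-standard-error allowances throughout.

## Known limitations

- The Laplace approximation can differ from exact marginal likelihood for
  very sparse subjects (few observations, large IIV); the quadrature
  cross-check covers the shipped designs only.
- The adolescent study effect is estimated from 10 subjects in the pooled
  design; as in the source analyses, its sign and size should be read with
  caution.
- Dosimetry regressions treat activity as the exposure surrogate; popPK-
  derived AUC is computed by the PK layer but deliberately not used as the
  regression exposure metric.
- No decay correction, BLQ handling, or saturable kinetics.
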