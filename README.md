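# lutadosim

Population pharmacokinetics and exposure–dosimetry simulation for Lu-177
DOTATATE radioligand therapy.

Lu-177 DOTATATE is dosed flat — 7.4 GBq per cycle, four cycles eight weeks
apart — and the organs at risk are the kidneys and bone marrow, with
radiation-tolerance thresholds taken from external-beam experience (kidney
23/29 Gy, marrow 2 Gy cumulative). Deciding whether that adult regimen is
safe in a new population (e.g. adolescents) hinges on three quantitative
pieces, all implemented here for pharmacometricians and clinical
pharmacologists:

1. **A population PK model** — two-compartment disposition with zero-order
   (infusion) input and first-order elimination, macro parameters
   $(CL, V_c, Q, V_p)$, log-normal inter-individual variability on $CL$ and
   $V_c$ (correlation $\rho$), additive residual error. The package provides
   the closed-form biexponential solution with superposition over dose
   events, exposure metrics (AUC, Cmax), population simulation,
   Laplace-approximation maximum-likelihood fitting (compiled inner problem),
   empirical Bayes estimates, covariate screening and prediction-corrected
   VPCs.

2. **Empirical exposure–dosimetry models** — per-cycle absorbed dose as a
   power law in administered activity and creatinine clearance, normalized at
   7.4 GBq / 99 mL/min:

   kidney = A·(activity/7.4)^B · (CrCL/99)^(C + β·adolescent),
   marrow = D·(activity/7.4)^E · (CrCL/99)^F,

   with proportional residual error, maximum-likelihood fitting, %RSE from
   the observed Fisher information, BIC model comparison (study effect on the
   kidney CrCL exponent) and dosimetry VPCs. Published estimates ship as
   `dosimetry_params_adult()` (A = 4.3, B = 0.66, C = −0.552; D = 0.246,
   E = 0.597, F = −1.11) and `dosimetry_params_pooled()` (A = 4.37,
   β = +1.58; D = 0.24).

3. **Monte Carlo engines** — the 240-scenario activity × CrCL grid (500
   virtual subjects per cell), virtual trials of 5 or 10 subjects (500
   trials) for sample-size evaluation, cohort-level threshold-exceedance
   summaries, and a flat-dosing check across body-weight strata.

A synthetic-data module (`generate_cohort()`, `generate_pk_dataset()`,
`generate_dosimetry_dataset()`) replaces the non-public trial data with
cohorts matched to the published demographic summaries and embeds the
generating truth, so every fit in the test suite is a parameter-recovery
experiment. IO helpers read and write NONMEM-convention longitudinal CSVs
and tidy dosimetry tables, and a YAML configuration plus a thin command-line
interface (`inst/cli/lutadosim.R`) tie the stages together.

## Worked example

```r
library(lutadosim)

p <- dosimetry_params_adult()

predict_kidney_dose(p, activity = 7.4, crcl = 99)
#> [1] 4.3
predict_marrow_dose(p, activity = 7.4, crcl = 99)
#> [1] 0.246
cumulative_dose(p, rep(7.4, 4), crcl = 55, organ = "kidney")
#> [1] 23.79243
```

At the reference point (7.4 GBq, CrCL 99 mL/min) the models return their
baselines: 4.3 Gy per cycle to the kidney and 0.246 Gy to the marrow. A
patient at the low end of renal function (CrCL 55 mL/min) accumulates
23.8 Gy in the kidneys over four cycles — under the 29 Gy threshold, which is
why 55 mL/min acts as the safety cutoff in the scenario grid.

Virtual trials of 5 adolescents (CrCL drawn from the adolescent-emulating
truncated normal, one proportional residual draw per subject on the 4-cycle
cumulative dose):

```r
res <- simulate_virtual_trials(p, crcl_distribution(),
                               trial_design(n_per_trial = 5, n_trials = 500),
                               thresholds = c(23, 29), seed = 1)
res
#> <exceedance_result> kidney, 500 trials of n=5
#>  threshold p_exceed_median
#>         23           0.052
#>         29           0.000
```

5.2% of 500 simulated 5-patient trials have a median cumulative kidney dose
above 23 Gy, and none above 29 Gy — well below the 20% limit used to judge
trial feasibility.

Fitting the dosimetry regression to a synthetic 47-adult dose-escalation
dataset recovers the generating model:

```r
set.seed(1)
coh <- generate_cohort(cohort_spec("adult", n = 47))
act <- sample(c(1.85, 3.7, 5.55, 7.4), 47, replace = TRUE)
rec <- generate_dosimetry_dataset(p, coh, activity = act)
fit_dosimetry(rec)
#> <dosimetry_fit> converged; -2LL total = 70.87, BIC total = 101.67
#> <dosimetry_params> kidney: 4.634*(act/7.4)^0.779*(crcl/99)^(-0.617+0*adol), b1=0.463
#>                    marrow: 0.2726*(act/7.4)^0.781*(crcl/99)^-0.747, b2=0.732
#> %RSE:
#> a_pop b_pop c_pop    b1 d_pop e_pop f_pop    b2
#>  9.54 12.60 45.88 15.23 16.85 17.78 46.50 26.79
```

One replicate of 47 subjects lands within sampling error of the generating
values (the wide %RSE on the CrCL exponents mirrors the precision reported
for the original 47-subject analysis); the median bias across 200 replicates
is checked in the test suite.

See `vignettes/methods.Rmd` for the models, assumptions, parameter defaults
and numerical choices, and for what the synthetic data do and do not emulate.

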