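# tacropop

Population pharmacokinetics of the once-daily extended-release tacrolimus
formulation in *de novo* adult kidney-transplant recipients.

Tacrolimus has a narrow therapeutic window (early post-transplant troughs of
5–10 ng/mL) and large between-patient variability. `tacropop` implements a
complete nonlinear mixed-effects modelling pipeline for this setting, built
for pharmacometricians and methodologists who want a tested, reproducible
implementation of the model and of every analysis stage around it:

* **Structural model** — closed-form two-compartment oral model with
  first-order absorption and lag time; multiple-dose superposition
  (`conc_profile()`), verified in the test suite against independent ODE
  integration.
* **Covariate model** — typical clearance
  `CL/F = (θ₁·θ₂^[non-carrier] − θ₃·AGE·[AGE>60]) · (BW/70)^0.75` with
  allometric scaling (exponent 0.75 for flows, 1 for the central volume) and
  CYP3A5 carrier status and age as clinical covariates; whole-blood
  concentrations standardized to a hematocrit of 45%
  (`standardize_hct()`), reflecting the near-complete erythrocyte binding of
  tacrolimus. Defaults in `pk_theta()`/`pk_omega()` are the published final
  estimates (typical CL/F 26.5 L/h for a CYP3A5*1 carrier ≤ 60 y at 70 kg).
* **Estimation** — Laplacian conditional estimation (FOCE-type, with
  interaction) of fixed effects, log-normal between-patient variabilities on
  CL/F and Vc/F and a proportional residual error (`pk_fit()`), with
  empirical-Bayes estimates, eta/epsilon shrinkage, RSEs, condition number,
  likelihood-ratio testing (`lrt_threshold()`) and forward-backward stepwise
  covariate selection (`covariate_search()`).
* **Diagnostics** — prediction-corrected visual predictive checks
  (`pcvpc()`) and a nonparametric bootstrap (`pk_bootstrap()`), both with
  `autoplot()` methods.
* **Exposure metrics** — linear-up/log-down trapezoidal AUC₂₄, trough
  extraction, dose-normalized metrics and geometric-mean summaries
  (`nca_metrics()`).
* **Dose-scenario simulation** — Monte-Carlo day-5 exposure distributions by
  dose × genotype × age × hematocrit stratum (`scenario_grid()`), the basis
  for starting-dose guidance.
* **Synthetic data** — a generator emulating the study design (138 subjects,
  29 with a rich 9-point day-5 profile, the rest trough-only on days
  5/10/15) and covariate distributions, so the full pipeline is testable
  without clinical data (`sample_covariates()`, `build_design()`,
  `simulate_dataset()`).

## Worked example

Simulate a 60-subject study from the published model, refit it, and ask a
dosing question:

```r
library(tacropop)
set.seed(42)
subjects <- sample_covariates(60)
design   <- build_design(subjects, design_spec(n_total = 60, n_rich = 15))
dataset  <- simulate_dataset(design, pk_theta(), pk_omega())

fit <- pk_fit(dataset)
fit
#> Population PK fit (two-compartment oral, Laplacian conditional estimation)
#>   60 subjects, 300 observations; OFV = 1220.767; convergence = 0
#>        term  estimate rse_pct fixed block
#>      theta1  27.64000   10.60 FALSE theta
#>        vc70 317.60000   14.50 FALSE theta
#>          vp 275.20000   25.10 FALSE theta
#>       cld70  34.72000   40.10 FALSE theta
#>          ka   2.00000      NA  TRUE theta
#>        alag   0.37200    9.03 FALSE theta
#>      theta2   0.62840   11.00 FALSE theta
#>      theta3   0.06146   26.90 FALSE theta
#>    omega_cl   0.24640   12.50 FALSE omega
#>    omega_vc   0.38890   30.00 FALSE omega
#>  sigma_prop   0.28660    4.96 FALSE omega
#>   eta shrinkage: CL 9.1%, Vc 53.0%; eps 8.7%
#>   condition number: 48.2
```

The generating values (θ₁ = 26.5, θ₂ = 0.666, Vc = 327 L, lag 0.341 h,
σ = 0.282, …) are recovered within their uncertainty; the high Vc shrinkage
is the expected signature of a design in which most subjects contribute only
troughs. `tidy(fit)` returns the parameter table as a tibble and
`glance(fit)` the one-row fit summary.

What trough and AUC would a CYP3A5 non-carrier aged ≤ 60 with normal
hematocrit reach on 6 mg once daily, on day 5?

```r
sc <- simulate_scenario(fit$theta, fit$omega, dose = 6,
                        genotype = "noncarrier", age = 55,
                        hct_range = c(40, 49), n = 1000, seed = 7)
sc
#> Dose-scenario simulation
#>  dose   genotype age hct_lo hct_hi    n ctrough_q1 ctrough_med ctrough_q3
#>     6 noncarrier  55     40     49 1000   6.300527    8.646924   11.32381
#>  auc24_q1 auc24_med auc24_q3 frac_ctrough_in_range frac_auc_over_1
#>  275.5853  320.4962 373.4169                 0.485               1
#>  frac_auc_over_2
#>            0.868
```

A median trough of 8.6 ng/mL sits inside the 5–10 ng/mL target, with about
half of simulated patients in range at this dose; the full 72-scenario grid
(`scenario_grid()` + `autoplot()`) reproduces the dose-by-covariate boxplot
layout used for starting-dose guidance.

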