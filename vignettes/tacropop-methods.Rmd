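---
title: "Population pharmacokinetics of once-daily extended-release tacrolimus: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of once-daily extended-release tacrolimus: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacropop)
```

## The problem

Tacrolimus is the backbone immunosuppressant of kidney transplantation. It
has a narrow therapeutic window (whole-blood troughs of roughly 5–10 ng/mL in
the early post-transplant period) and large between-patient variability, so
the starting dose of the once-daily extended-release formulation is hard to
choose well. Three patient-level factors dominate that variability in de novo
recipients:

* **CYP3A5 genotype** — carriers of at least one functional *1 allele clear
  the drug substantially faster than *3/*3 non-carriers;
* **age** — clearance declines in patients older than about 60 years;
* **hematocrit** — tacrolimus is almost entirely sequestered in erythrocytes
  (blood/plasma ratios up to ~50), so the whole-blood concentration at a
  fixed pharmacologically active unbound concentration rises roughly in
  proportion to hematocrit. Hematocrit is low right after surgery and climbs
  week by week, which makes raw whole-blood concentrations drift for reasons
  that have nothing to do with drug elimination.

`tacropop` implements a nonlinear mixed-effects model of this situation
end-to-end: structural model, covariate model, estimation, diagnostics,
non-compartmental exposure metrics, and a Monte-Carlo dose-scenario
simulator, together with a synthetic data generator that emulates the
sampling design of a de novo transplant study, so that every stage of the
pipeline can be tested without access to clinical data.

## Structural model

Drug disposition is a two-compartment open model with first-order absorption,
an absorption lag time, and linear elimination from the central compartment.
All parameters are apparent (oral) quantities — CL/F, Vc/F, Vp/F, CLD/F —
because no intravenous data exist; the bioavailability F is fixed at 1.
The absorption rate constant Ka is fixed at 2 h⁻¹: with a first post-dose
sample at 0.5 h the absorption phase is too sparsely sampled to estimate Ka,
and richer absorption models (transit chains, Erlang/gamma profiles) are
deliberately out of scope because they over-parameterize data of this
design.

The single-dose solution is the closed-form tri-exponential

$$C(t) = D\,\big(A e^{-\alpha\tau} + B e^{-\beta\tau} + C e^{-K_a\tau}\big),
\qquad \tau = t - t_{\mathrm{lag}},$$

with the hybrid constants computed from the micro rate constants
(`hybrid_constants()`), and multiple dosing handled by superposition
(`conc_profile()`). Doses are in mg, volumes in L; the mg→µg conversion
(×1000) is applied once at this boundary so concentrations come out in
ng/mL. The closed form was chosen over numerical integration for speed — the
estimation layer evaluates it millions of times — and an ODE integration of
the depot/central/peripheral system is retained in the test suite as an
independent oracle (agreement to < 10⁻⁶ relative error over random parameter
sets).

Numerical choices: when Ka collides with a disposition exponent the closed
form is ill-conditioned; `hybrid_constants()` raises a degeneracy error at a
relative separation of 10⁻⁸ rather than silently perturbing. Inside the
estimation hot path, transient near-collisions during optimization are
guarded by clamping the offending denominator at 10⁻¹⁰.

## Covariate model and hematocrit standardization

Typical values are built from the fixed effects as

$$\mathrm{CL/F} = \big(\theta_1\,\theta_2^{[\text{non-carrier}]}
  - \theta_3\,\mathrm{AGE}\cdot[\mathrm{AGE}>60]\big)\,(BW/70)^{0.75},$$
$$\mathrm{Vc/F} = \theta_4\,(BW/70), \qquad
  \mathrm{CL_D/F} = \theta_5\,(BW/70)^{0.75}, \qquad \mathrm{Vp/F} = \theta_6,$$

with allometric exponents fixed at 0.75 (flows) and 1 (central volume), and
Vp/F unscaled (bodyweight scaling of Vp degraded the precision of the Vc
random effect and is not part of the final model). Defaults in `pk_theta()`
are the final published estimates (θ₁ = 26.5 L/h, θ₂ = 0.666, θ₃ = 0.0562
L/h per year, Vc = 327 L, Vp = 298 L, CLD = 51.9 L/h, ALAG = 0.341 h).

Two modelling decisions here were genuinely open:

* **The age term uses full age in years**, exactly as the breakpoint
  equation is written, not (AGE − 60). This creates a step in typical CL/F
  at the breakpoint (26.5 → 23.1 L/h for a carrier crossing 60). We
  implement the equation literally; the discontinuity is a property of the
  published model, not of this implementation.
* **The hematocrit standardization formula is not printed in the source
  material**, which cites precedent work. We adopt the linear
  erythrocyte-partition rescale \(c_{45} = c_{\mathrm{obs}} \cdot 45 /
  \mathrm{HCT}\), justified by the near-complete red-cell binding: if
  essentially all drug is in erythrocytes, whole-blood concentration is
  proportional to hematocrit at a fixed unbound concentration. A nonlinear
  red-cell binding variant exists in the literature but was evaluated and
  not retained in the model we implement; the standardization is therefore
  kept as a simple, exactly invertible pair
  (`standardize_hct()` / `destandardize_hct()`).

Between-patient variability is log-normal on CL/F and Vc/F
(`CL_i = TV_CL e^{\eta_1}`), residual error is proportional
(`y = f(1+\varepsilon)`). The ω values are stored as SDs of the log-scale
effects; the conventional "%CV" report is 100·ω (exact CV is
\(\sqrt{e^{\omega^2}-1}\), 33.0% at ω = 0.321 — the difference is documented
rather than hidden). Simulated observations are not truncated at zero:
truncation would bias the error model; the synthetic-data generator redraws
the rare negative sample instead, and the scenario simulator clips negative
noisy samples to zero only where the log-trapezoid integration requires
non-negative input.

## Estimation

`pk_fit()` maximizes a Laplacian approximation to the marginal likelihood:
for each subject the penalized deviance is minimized over (η₁, η₂) and the
curvature at the mode supplies the integral correction, with the residual
variance evaluated at the individual prediction (i.e. conditional
estimation *with interaction*). This is a deliberate numerical-method
substitution for the FOCE-I implementation used in the original analysis —
the model, not the estimator brand, is the scientific content — and the
package asserts equivalence at the level of parameter recovery, not OFV
equality. The OFV excludes the n·log 2π constant, so OFV differences can be
compared with the usual chi-square thresholds (3.841, 7.879, 10.83 for 1
df).

Implementation notes:

* All subjects are advanced simultaneously by a vectorized safeguarded
  Newton iteration with warm-started modes, finite-difference gradients and
  Hessians (step 10⁻³), step clamping at ±3 and a halving line search.
* The outer optimization runs on log-transformed parameters (all are
  positive) under `nlminb`, with a second quasi-Newton pass and then a
  Nelder-Mead restart if convergence is not clean. Observations whose
  prediction falls below 10⁻⁶ ng/mL would make a proportional error model
  degenerate; the floor keeps the objective finite and such records are
  design errors upstream (samples scheduled before the lag time).
* Standard errors come from the central finite-difference Hessian of the
  OFV (step 5·10⁻³ on the transformed scale), the condition number is the
  eigenvalue ratio of the correlation matrix of the estimates, and the
  random-effect matrix is diagonal (the published model reports no
  covariance term).

`covariate_search()` implements the forward (ΔOFV ≥ 3.841) / backward
(ΔOFV ≥ 10.83) stepwise procedure with the additional clinical-significance
rule that the targeted parameter's between-patient variance must fall by at
least 10%. The reduction is computed on the variance scale (ω²): the
published per-covariate reductions (≈16% for genotype, ≈16% for hematocrit
standardization) are numerically consistent with variance-scale arithmetic
under this model, whereas on the SD scale the same effects produce only
~8% reductions, which would contradict the reported decisions.

## Diagnostics

`pcvpc()` is a prediction-corrected visual predictive check: simulated
replicates of the original design, correction of each observed and simulated
value by the ratio of the bin-median population prediction to the row's own
population prediction, and percentile bands with confidence intervals.
Binning is by nominal time after the preceding dose (the scheduled design
offsets), not data-driven quantiles, because the design is fixed. The
percentile pair is configurable, with (5, 50, 95) as the default display.
`pk_bootstrap()` resamples subjects with replacement, refits from the
original estimates, and reports percentile confidence intervals; failed
replicates are counted and more than 20% failures flags the result
unstable. Eta and epsilon shrinkage follow the usual definitions
(`100(1 - SD(EBE)/\omega)`, `100(1 - SD(IWRES))`).

## Dose-scenario simulation

`simulate_scenario()` reproduces the dose-individualization experiment:
once-daily doses at 0, 24, …, 96 h, evaluation of the fifth dosing interval
[96, 120] h ("day 5") on a dense 0.1-h grid, per-subject random effects,
hematocrit drawn uniformly within its stratum and held constant, residual
error applied to the sampled concentrations (switchable off for pure-model
summaries, since whether the original simulations included it is not
recoverable), conversion to the observed scale via `destandardize_hct()`,
and non-compartmental metrics: C_trough at 120 h and AUC₂₄ over [96, 120] by
the linear-up/log-down trapezoid. Day 5 is operationalized as the fifth
dosing interval rather than steady state, and bodyweight is fixed at the
70-kg reference; the elderly stratum is exactly 80 years. The default grid —
doses 5–7.5 mg in 0.5-mg steps × carrier/non-carrier × ages {55, 80} ×
hematocrit strata {20–29, 30–39, 40–49}% — yields 72 scenarios, each with an
independent, position-keyed seed substream.

## Synthetic data generator

`sample_covariates()`, `build_design()` and `simulate_dataset()` emulate the
study conditions: 138 subjects of whom 29 contribute a 9-point day-5 profile
(pre-dose and 0.5, 1, 2, 4, 8, 12, 20, 24 h after the day-5 dose) plus
troughs on days 10 and 15, the remainder troughs on days 5/10/15 only;
once-daily dosing at 0.1 mg/kg rounded to 0.5 mg; age from a truncated
normal (mean 54, SD 13, range 19–82 — the SD is our choice, made once to
respect the published median and range, as only those are reported);
bodyweight log-normal (median 70.5 kg, σ_log 0.18, truncated to 44–109 kg);
CYP3A5 genotype frequencies 2.2/12.3/85.5%; hematocrit rising over occasions
as a clipped random walk (day 5 ~ N(29.7, 4), increments N(1.6, 1.5))
reproducing the rising occasion medians. Covariates are drawn independently
because only marginals are published — a documented simplification: real
covariates are correlated (e.g. weight with age and sex), so covariate-joint
phenomena are outside what passing tests demonstrate. An optional
therapeutic-drug-monitoring mode titrates subsequent doses by
(7.5/trough), clipped to [0.5×, 2×] and rounded to 0.5 mg, whenever an
observed trough leaves 5–10 ng/mL; it is off by default because estimation
experiments need dose histories independent of the simulated observations.

The stated record counts follow from the design: 29 × 9 = 261 day-5 records,
29 × 2 = 58 additional rich-subject troughs, 109 × 3 = 327 trough-only
records, 646 scheduled observations in total. (The source material's own
record totals are mutually inconsistent — 1,067 total against
261 + 233 + 573 = 1,067 but also "634" rich-subject values and "1,408"
troughs — so the generator follows the stated design, not the stated
totals.)

## What the tests do and do not show

The acceptance-level experiments are simulation-based: data are generated
from the published final estimates under the published design and refitted.
They demonstrate that the implementation is self-consistent (the estimator
recovers the generating values within the published precision; the search
machinery detects effects of the published size with the published
thresholds; shrinkage reflects design information content). They cannot
demonstrate anything about the clinical data themselves: real-data
quantities (objective-function drops, variance reductions, exposure tables)
depend on the unpublished dataset and are deliberately not reproduced.

Problem sizes used by the packaged experiments, chosen as a balance between
Monte-Carlo error and the cost of a documented, re-runnable suite: one
138-subject refit plus five replicate refits for the recovery checks; ten
simulated datasets per arm (effect present/absent) for the covariate-search
power check, with the structural disposition parameters held at their
generating values so each search step estimates only the parameters the
decision depends on; 40-subject designs for the shrinkage contrasts;
150–2000 subjects per scenario cell elsewhere. The dose-scenario engine
defaults to the full 1,000 profiles per scenario.

## Known limitations

* The estimator is a Laplace approximation; like all conditional-estimation
  methods it carries small finite-sample biases. Parameter-recovery tests
  use tolerance bands derived from the published standard errors, which
  absorb them.
* Inter-occasion variability is not implemented (tested in the source
  analysis, not retained in the final model), so day-to-day within-patient
  drift beyond hematocrit is not emulated.
* The hematocrit standardization is linear; saturable red-cell binding is
  not modelled.
* CYP3A5 is collapsed to carrier vs non-carrier; the three-genotype effect
  is not estimable at realistic *1/*1 frequencies and is not attempted.
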