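---
title: "Methods: population PK of vancomycin in NICU neonates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of vancomycin in NICU neonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovanc)
```

## The model

`neovanc` implements a hierarchical (nonlinear mixed-effects) analysis of
intravenous vancomycin concentrations in neonatal intensive-care patients.
The structural model is a one-compartment disposition with zero-order
(infusion) input and first-order elimination, parameterised by clearance
`CL` (L/h) and apparent volume `V` (L), with `k_e = CL/V`. Because the
kinetics are linear, the concentration at any time is the exact
superposition over the dose history: during an infusion at rate $R_0$ the
contribution is $(R_0/CL)(1 - e^{-k_e \Delta t})$, and after the infusion
ends that value decays exponentially. Steady state is reached by explicitly
superposing the full dose history — there is no steady-state shortcut flag,
so "sampling after the fourth dose" is a property of the design, not an
approximation in the model.

Between-subject variability is log-normal, $P_i = P_{TV} e^{\eta_i}$ with
$\eta_i \sim N(0, \omega^2)$. Residual variability supports the additive,
proportional and combined error models; the vancomycin analysis uses the
proportional model $Y = F(1 + \varepsilon)$.

Covariates act multiplicatively on the typical values. Continuous
covariates use a power form $(x/x_{ref})^{\theta}$ with an explicit
centering constant; binary covariates use an exponential indicator
$e^{\theta I}$. The shipped final model for this population is

$$CL = 0.14 \cdot (WT/2.12)^{1.13} (Scr/30.52)^{-0.15} (DFI/367.18)^{0.14}
  e^{-0.20\,DA} e^{\eta_{CL}}, \qquad V = 1.04 \cdot (WT/2.12)^{1.07},$$

with proportional residual error of 18% CV and inter-individual variability
on CL of 4.97% CV (expressed as $100\,\omega$; the log-normal convention
$100\sqrt{e^{\omega^2}-1}$ is available via `tidy(fit, cv_convention =
"lognormal")` and agrees to four decimals at this magnitude). The centering
constants 2.12 kg / 30.52 µmol/L / 367.18 mL are part of the model
specification and are never recomputed silently; when building a model for
new data, `default_candidates()` centres at the dataset medians and records
them in the spec. The final model carries IIV on CL only; the base model
carries IIV on CL and V (the V component is weakly identified from
trough/peak sampling and collapses during estimation, which is why the
final model drops it).

## Estimation

`pk_fit()` maximises a first-order conditional (FOCE) approximation with
interaction to the marginal likelihood. For subject $i$ with conditional
mode $\hat\eta_i$ of the penalised extended-least-squares objective

$$\sum_j \left[ \frac{(y_{ij} - f_{ij}(\eta))^2}{R_{ij}(\eta)}
  + \log R_{ij}(\eta)\right] + \eta^\top \Omega^{-1} \eta,$$

the objective function value is

$$\mathrm{OFV} = \sum_i \left[ \log\det\Sigma_i
  + r_i^\top \Sigma_i^{-1} r_i + n_i \log 2\pi \right], \qquad
  \Sigma_i = G_i \Omega G_i^\top + R_i(\hat\eta_i), \quad
  r_i = y_i - f_i(\hat\eta_i) + G_i\hat\eta_i,$$

with $G_i = \partial f_i/\partial\eta$ at $\hat\eta_i$. The $n\log 2\pi$
constant is retained; every modelling decision in the workflow (covariate
gates, model comparison) uses OFV differences, which are unaffected by it.
The residual variance is evaluated at $\hat\eta_i$ (interaction). One
consequence worth knowing: under proportional error the $\log R(\eta)$ term
shifts the conditional mode of an exactly-typical subject away from zero by
$O(\omega^2)$ times the prediction elasticity — this is a property of the
estimator, not a bug, and it vanishes under additive error.

Numerics. The inner $\eta$ problem (dimension 1–2) is solved by damped
Newton with finite-difference derivatives, step-halving line search,
gradient tolerance $10^{-8}$, started from the warm-started previous mode
and from zero, keeping the lower objective (deterministic). The outer
problem runs BFGS on transformed parameters — log scale for `tvCL`, `tvV`,
$\omega$, $\sigma$; natural scale for covariate coefficients — with
relative OFV tolerance $10^{-10}$. Failed or singular subject covariances
yield a large penalty rather than an abort inside the optimiser. The inner
and outer loops, and the superposition kinetics, are implemented in C++
(RcppArmadillo); the residual variance is floored at $10^{-12}$ to guard
$f \to 0$ under proportional error. Standard errors come from the inverse
central-difference Hessian of OFV/2 at the optimum (relative step 1%, with
a 0.1 floor); a non-PD Hessian is eigenvalue-adjusted and flagged.

Accuracy of the approximation: against 64-node Gauss–Hermite quadrature the
FOCE objective agrees to well under 0.1 OFV units on two-subject toys with
post-infusion sampling at $\omega \le 0.3$, and converges to the exact
$-2\log L$ as $\omega \to 0$. Under the steady-state *trough* design the
prediction is highly elastic in $\eta$ (elasticity ≈ 2–3), and the
linearisation error grows to a few tenths of an OFV unit at
$\omega \ge 0.1$ — immaterial for $\Delta$OFV-based decisions at the 3.84 /
7.88 gates but visible when comparing absolute OFVs across estimators.

## Covariate selection

`screen_covariates()` and `stepwise_covariates()` implement univariate
screening and stepwise forward-addition / backward-elimination with
likelihood-ratio gates: inclusion requires an OFV drop greater than 3.84
($p < 0.05$, df 1), retention requires that removal raises the OFV by more
than 7.88 ($p < 0.005$, df 1). Each relation counts one degree of freedom;
the three-level critical-illness score enters as two binary indicators.
Candidate fits warm-start from the incumbent estimates; the selected model
is verified with a cold-start refit. Ties are broken lexicographically by
(parameter, covariate) so selection is reproducible. No collinearity guard
is applied — the synthetic cohorts deliberately reproduce the strong
weight–PMA (0.87) and weight–fluid-input (0.73) correlations so that
selection behaviour under collinearity is realistic.

## Diagnostics

* **Bootstrap** (`pk_bootstrap()`): subjects are resampled with replacement
  to the original cohort size and the model refitted per replicate
  (default 1,000 replicates, configurable); parameters are summarised by
  the median and 2.5–97.5 percentile interval of successful fits, and the
  result is flagged unreliable when more than 20% of fits fail.
* **VPC** (`pk_vpc()`): the 5th/50th/95th observed percentiles by
  time-after-dose bin (decile edges by default, small bins merged) are
  overlaid on the 2.5–97.5 percentile band of the same percentiles across
  simulated replicates (default 1,000). Note the band is the
  between-replicate predictive interval: it converges to the predictive
  spread as the simulation count grows; what improves with more simulations
  is the Monte-Carlo precision of the band edges.
* **NPDE** (`pk_npde()`): per subject, observed and simulated vectors are
  decorrelated with the inverse Cholesky factor of the empirical simulation
  covariance; the rank-based $pd$ uses a half-count correction
  $1/(2 n_{sim})$ at the extremes; NPDE = $\Phi^{-1}(pd)$. Three tests are
  reported — $t$-test for mean 0, a chi-square–based variance test against
  1, Shapiro–Wilk for normality — plus a Bonferroni-adjusted global
  $p = \min(1, 3\min p)$. Both raw and adjusted values are printed, since
  reporting conventions differ across software.
* **External validation** (`prediction_errors()`): population predictions
  ($\eta = 0$, no Bayesian updating — the stricter, prior-free convention)
  give per-observation relative errors $100(PRED-OBS)/OBS$, summarised as
  MPE, MAPE, F20 and F30 with inclusive boundaries.

## Dosing

At steady state $AUC_{24} = \text{daily dose}/CL$, so the efficacy target
$AUC_{24}/MIC \ge 400$ is met exactly by $\text{dose} = 400 \cdot MIC
\cdot CL$. `dose_table()` builds the initial-dose grid over serum
creatinine × daily fluid input × diuretic status: per cell it draws
patients with body weight uniform on 1–5 kg and $\eta_{CL} \sim
N(0,\omega^2)$, computes each patient's target-attaining per-kg dose, and
reports the cell **median**, rounded half-up to integer mg/kg/day. The
choice of weight distribution and of the median as the summary is a design
decision of this package — there is no canonical way to collapse a 1–5 kg
weight range into one per-kg figure — so exact grid values depend on it,
while the structure
(doses fall with creatinine, rise with fluid input, and are lower under
diuretics) and the $400 \times CL$ identity do not. The median rule implies
roughly 50% target attainment at the unrounded dose; integer rounding moves
attainment by a few percent either way. Residual (assay) error is excluded
from dose derivation because steady-state AUC depends on clearance only.

## Synthetic cohorts

`sim_covariates()` draws continuous covariates from a Gaussian copula with
log-normal margins matched by (median, IQR) to the observed neonatal
cohort (weight median 1.98 kg, IQR 1.35–2.98; creatinine 32.48 µmol/L;
daily fluid input 364 mL; etc.). The copula correlation for each
constrained pair is back-solved so the *Pearson* correlation of the
log-normal margins hits the reported targets (weight–PMA 0.8696,
weight–DFI 0.7274); unconstrained pairs involving a common correlated
neighbour receive the conditional-independence implied value (e.g.
PMA–DFI $= \rho_{WT,PMA}\rho_{WT,DFI}$), which keeps the matrix positive
definite — zeros there would be jointly infeasible and an eigenvalue
repair would attenuate the constrained pairs. Diuretic use is Bernoulli
(prevalence 0.333), other comedications and the critical-illness classes
follow the observed prevalences.

Regimens follow the clinical rule: 10–15 mg/kg per dose (uniform, rounded
to 0.5 mg), interval 8 or 12 h with equal probability, 1-h infusions, six
doses. Sampling attaches to the fifth dose — the first dose after the
stated four-dose run-in — at 0.5 h before the dose (trough) and 0.5 h
after the end of the infusion (peak). By default 52% of subjects
contribute trough only, matching the observed share of trough samples;
recovery experiments that need maximum information set `trough_only = 0`.
Observations outside the 2–50 mg/L assay calibration range are flagged
excluded — flagged, never altered or dropped from the file.

What the generator does *not* emulate: time-varying covariates (covariates
are frozen at treatment start, as collected), irregular clinical sampling
times, assay rounding, missing covariates, and any outcome process (AKI,
efficacy). Passing recovery tests on these cohorts therefore demonstrates
the estimator and workflow are correct under the stated design, not that
the published estimates are reproducible from the real data.

A note on sampling noise: a single 112-subject cohort estimates a
log-normal median with ≈7% relative error, so the generator's calibration
is asserted on averages over cohorts; any single cohort can sit 10–15% off
a target median.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and is byte-reproducible
given it. The test suite and the acceptance script use study-scale
problems where the science requires them (112-subject cohorts for recovery
and NPDE calibration, ten replicate fits) and reduced scales where only
the mechanism is being checked (30–60 subject cohorts for selection and
bootstrap structure, 30–100 replicates for level checks); each scale is
stated where it is used.

## Known limitations

* FOCE, not SAEM or full Bayes; $\Omega$ is diagonal (matching how the
  variability was reported) and no M3/censored-likelihood handling —
  out-of-range observations are excluded, with counts logged.
* Absolute OFVs are comparable only within this package (the $n\log 2\pi$
  constant and conditional-mode conventions differ across software);
  $\Delta$OFV logic is convention-free.
* Two-compartment disposition and nonlinear elimination are out of scope
  (the one-compartment model is the accepted structure for this sparse
  neonatal design).
* External validation uses population predictions; centres that apply
  Bayesian updating will see smaller errors than `prediction_errors()`
  reports.
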