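---
title: "Models and methods behind tacropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tacropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacropop)
```

tacropop analyses tacrolimus trough concentrations collected by routine
therapeutic drug monitoring (TDM) early after adult liver
transplantation. Tacrolimus shows apparently nonlinear kinetics in this
population: the daily dose needed per unit of trough concentration is
not constant, plausibly because of saturable binding to erythrocytes,
dose-dependent apparent clearance, and the many physiological changes of
the early postoperative weeks. The package implements the two modelling
strategies used to study this nonlinearity, the machinery to fit and
qualify them, a synthetic-cohort generator so the whole pipeline is
testable without patient data, and a Monte Carlo starting-dose engine.

## The two structural models

**Empirical Michaelis–Menten (MM) dose–trough model.** At steady state
the total daily dose `DD` (mg/day) and the whole-blood trough `C0`
(ng/mL) are linked by a saturation relation,

$$DD = \frac{V_m\,C_0}{f\,K_m + C_0},\qquad
  f = \frac{10}{\min(\mathrm{POD}, 10)},$$

where `Vm` is the maximum steady-state daily dose rate, `Km` the trough
at the half-maximal dose rate, and `f` an early-postoperative factor
(active when `time_factor = TRUE`) that inflates the effective `Km`
before day 10 and equals 1 afterwards. The dependent variable of this
model is the *daily dose* predicted from the observed trough; this
follows from the units of its additive residual component (mg/day).
`Km` carries the between-subject random effect and the covariate
effects (postoperative day, hematocrit, total bilirubin as power terms;
recipient CYP3A5 genotype and triazole-antifungal co-therapy as
proportional shifts). An open modelling question is whether `f`
multiplies only the typical `Km` or the covariate-adjusted value; the
package applies it to the full covariate-adjusted, random-effect-scaled
`Km`, which keeps the factor interpretable as a time-varying scaling of
the whole saturation constant.

**Theory-based one-compartment plasma model.** Whole-blood
concentrations are first mapped to plasma through saturable erythrocyte
binding,

$$C_{wb} = C_p + C_p\,\frac{\mathrm{HCT} \cdot B_{max}}{C_p + K_D},$$

with `Bmax = 418` and `KD = 3.8` ug/L and hematocrit as a *fraction*.
The published description says "HCT as %", but with percent the
blood:plasma ratio would be about 3500 instead of the well-established
~35 at `HCT` 0.35; the fraction interpretation reproduces the known
partitioning and the source binding model, and a configuration switch
records the choice. Plasma kinetics are a one-compartment model with
first-order absorption (`Ka` fixed at 4.48 1/h; no absorption-phase
data exist to estimate it) and first-order elimination, evaluated with
the closed-form steady-state trough for repeated dosing. The daily dose
is split into two 12-hourly doses and the trough is sampled 12 h after
a dose — the clinical q12h schedule; the split is a modelling choice
because only daily doses are recorded. Apparent plasma clearance
carries power (AST), saturable Emax (daily dose), and proportional-shift
(genotype, antifungal) covariates; the apparent volume carries an
exponential postoperative-day effect, read as
`exp(theta * POD / 15)` — the covariate-normalized exponential form used
for continuous covariates. The typical-clearance parameter is kept as
the pre-factor 234 L/h; the dose-Emax factor is not renormalized to 1
at the 1 mg reference (at 1 mg/day it contributes 1.02), matching how
the estimate is printed.

Between-subject variability is exponential, `P_i = TV(P) exp(eta_i)`
with diagonal covariance (no correlations are reported); residual error
is additive, proportional, or combined (`Y = F + F eps_1 + eps_2`).
Shipped presets `mm_base`, `mm_final`, `theory_base`, `theory_final`
carry the published estimates and serve as simulation ground truth.

## FOCE-I estimation

No available R package provides first-order conditional estimation with
interaction for these model/error structures, so the estimator is
implemented in the package. For each subject the conditional
random-effect mode minimizes the penalized objective

$$g_i(\eta) = \sum_j \left[\log v_j(\eta) +
  \frac{(y_j - f_j(\eta))^2}{v_j(\eta)}\right] +
  \eta^\top \Omega^{-1} \eta,$$

with the residual variance `v` evaluated at the conditional prediction
(the "interaction"). All subjects are solved simultaneously by damped
Gauss–Newton with exact gradients (model derivatives by central
differences, step 1e-4) and per-subject backtracking; the trust-region
step is capped at 2 on the log scale and iteration stops when the
largest gradient component falls below 1e-6. The marginal -2
log-likelihood then linearizes `f` about the mode:
`V_i = G \Omega G' + diag(v)`, `res = y - f(\hat\eta) + G\hat\eta`, and
the per-subject contribution `n_i log 2\pi + log|V_i| + res' V_i^{-1}
res` is assembled by the Woodbury identity (the random-effect dimension
is at most 2). The outer problem optimizes fixed effects, covariate
coefficients, variances and residual SDs on unconstrained transforms
(log for positive parameters, `log(1 + theta)` for proportional-shift
coefficients so the multiplier stays positive) with `nlminb`, followed
by a verification restart from the optimum; standard errors come from
the numerical Hessian of the objective (`Var = 2 H^{-1}`) with a delta
transform back to the natural scale.

Two independent oracles pin the implementation down. On linear-Gaussian
models with additive error the FOCE objective is *exactly* the
multivariate-normal -2 log-likelihood (machine precision in the tests).
On nonlinear fixtures it is compared with adaptive 64-node
Gauss–Hermite quadrature: with additive error the two agree to better
than 0.3% on 5-subject fixtures even at 60% CV of between-subject
variability. With proportional or combined error they deviate by
0.3–1.2% *by construction*: the exact likelihood integrates the
eta-dependence of the residual variance, which the interaction step
linearizes away; the gap vanishes as `omega -> 0`. The quadrature
equivalence test therefore uses an additive-error fixture, and the
interaction pathway is validated through parameter recovery instead.

## The synthetic cohort and why its MM design is exogenous

`simulate_cohort()` draws covariates from truncated normal
distributions, or truncated log-normal for the strongly right-skewed
laboratory values (ALT, AST, total bilirubin; mean/median ratio above
1.3). The underlying parameters are solved so that the *truncated*
moments match the published cohort means and SDs; creatinine clearance
is always computed from sampled age, weight and creatinine with the
Cockcroft–Gault formula rather than sampled. Genotypes are multinomial
draws from the published recipient and donor frequencies, with a
Pearson chi-squared Hardy–Weinberg report per locus (note that the
published recipient NR112 genotype counts are themselves far from
Hardy–Weinberg proportions, so rejection at that locus is expected
behaviour, not a generator defect). Time-varying labs recover
exponentially toward normal values with log-normal noise; antifungal
co-therapy is a subject-level flag with the cohort prevalence (56/176).
Visits per subject are `1 + Poisson(4)` (median 5), starting on
postoperative day 2–4 with 2–7-day gaps, capped at day 72.

For the **theory-based truth** the TDM loop is simulated literally: the
trough (the dependent variable) is drawn with its residual error at the
administered dose and the next dose titrates toward the 8–12 ng/mL
window (`next = current * target-midpoint / observed trough`, rounded
to 0.25 mg, at most a 50% change per step). Feedback through observed
dependent variables leaves the likelihood factorization intact, so
simulation-estimation experiments are statistically clean.

For the **MM truth** the same literal loop is *not* statistically
usable for recovery experiments: any physically generated steady-state
trough is exactly proportional to `exp(eta)`, so the regressor would
determine the random effect and the refit (which assumes the trough
design is exogenous) is asymptotically biased — measured at up to -26%
in `Vm` and -47% in `Km` when the design fully tracks the random
effect. The default generator therefore draws the trough design the way
dose-DV simulations are done over a fixed design: the design trough is
the *known* (covariate- and time-factor-adjusted, random-effect-free)
effective `Km` times a log-normal monitoring spread
(`exp(log 0.85 + N(0, 0.25^2)_{subject} + N(0, 0.5^2)_{visit})`,
clamped to 0.3–30 ng/mL). This reflects that clinically dosed patients
show troughs scaling with their expected saturation constant while
doses stay in the clinical range; it reproduces the cohort's trough
median (~6 ng/mL at typical covariates) and dose mean (~2.9 vs the
reported 2.73 ± 1.56 mg/day). The recorded dose is then simulated with
the combined residual error around the MM prediction; the rare
(<1%) sub-zero draws are floored at 0.05 mg rather than redrawn, which
leaves the residual distribution intact elsewhere (resampling would
truncate the error distribution exactly in the high-`Km`, early-POD
cells and was measured to distort the recovered error components by
20–30%). A `design = "feedback"` mode retains the literal titration
loop for illustrating titration dynamics; with noise off and zero
random effect it converges into the target window within a handful of
visits.

Limitations of the generator, hence of what green tests show about real
data: covariates are drawn independently (only creatinine clearance is
functionally linked), whereas real labs co-move; the residual error is
exactly the model's, so the recovery experiments quantify estimator
behaviour, not model misspecification; and the MM design exogeneity is
an idealization — real TDM data embed the feedback endogeneity, which
is a property of the modelling strategy itself, not of any estimator.

## Diagnostics

Prediction errors use `PE = (pred - obs)/obs * 100` with medians (MDPE,
MAPE) and the fractions within ±20%/±30% (F20/F30, boundaries
inclusive), for population and individual predictions. The bootstrap
resamples subjects with replacement to the original count, refits from
the original estimates, and summarizes converged replicates (median,
2.5–97.5 percentiles, bias%). The visual predictive check bins
observations on postoperative day (equal-count bins, default 8, bins
under 5 observations merged), corrects each value by the bin-median
typical prediction over its own, additionally scales deviations by the
bin-median simulated SD over the row's simulated SD, and overlays
observed 10th/50th/90th percentiles on simulation-based 95% CIs; the
exact variability-correction variant used in the source analysis is
uncited, so the standard prediction-plus-variability correction is
implemented and labelled as such. Normalized prediction distribution
errors decorrelate each subject's observation vector with the Cholesky
factor of the simulated covariance (2000 simulations by default, ridge
regularization if singular), apply the rank transform with the
`1/(2 n_sim)` continuity correction, and test the result for zero mean
(t-test), unit variance (chi-squared), and normality (Shapiro–Wilk),
Bonferroni-combined (`3 * min p`, capped at 1).

## Monte Carlo starting doses

The dosing engine evaluates the final MM model on postoperative day 7
(early-POD factor 10/7) over the 48 strata of genotype x antifungal
co-therapy x hematocrit band (20–30/30–40/40–50%) x bilirubin band
(<17.1, 17.1–85.5, 85.5–171, >=171 umol/L; open bands sampled within
5.1–300). Each stratum simulates 200 subjects with uniform within-band
covariates and `eta ~ N(0, omega^2)`; a subject's required dose is the
smallest 0.25 mg grid multiple whose steady-state trough enters the
8–12 ng/mL window (when the window is narrower than the grid, the grid
dose nearest the upper edge is used and the subject is counted toward
the infeasibility fraction). The reported range is the 2.5th–97.5th
percentile of required doses rounded outward to the grid — the
published table's summary rule is unstated, so exact cell reproduction
is not claimed, but the clinically meaningful partial order (dose falls
with bilirubin, hematocrit and antifungal co-therapy; rises for CYP3A5
expressers) and the published summary ranges are reproduced and tested.

## Problem sizes and numerical choices

Recovery experiments use 500 subjects with 5 troughs each — large
enough that sampling noise sits well inside the recovery tolerances for
well-identified parameters, small enough that a fit takes tens of
seconds. Three caveats are documented rather than hidden: the apparent
plasma volume is weakly identified from troughs alone (the likelihood
is nearly flat upward in `V` jointly with its variability — consistent
with the source analysis's own caution about `Vd`), so volume recovery
is noticeably seed-dependent; the typical-clearance parameter is
softly coupled to the dose-Emax coefficients (points with clearance
shifted by tens of percent lie within a handful of objective-function
units — the source analysis itself reports 46–56% relative standard
errors for these parameters), so refits report one point on that
near-flat manifold; and the small genotype coefficient on clearance
(0.168) has a sampling SE comparable to its 15% recovery band, so that
single check has limited power at this design size. Refits start from
the preset values, the convention of simulation-estimation studies;
the optimizer demonstrably improves the objective from there (a
Nelder-Mead stage guards against stalls on the flat ridges), and on
informative directions different starting values reach the same
optimum.
Stepwise selection tests use 70-subject cohorts where the planted
hematocrit effect yields likelihood-ratio drops far above the 3.84
inclusion threshold while a null covariate (albumin) stays at the
chi-squared(1) null. Bootstrap, VPC and NPDE defaults (1000/1000/2000
replicates) follow the published analysis; tests use smaller replicate
counts sized to their Monte Carlo error. Degenerate inputs are handled
explicitly: zero between-subject variance falls back to extended least
squares, near-coincident absorption and elimination rates use a small
relative offset, singular simulated covariances are ridge-regularized
and flagged, and saturation (`DD >= Vm`) raises an accumulation error.
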