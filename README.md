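# tacropop

Population pharmacokinetics of tacrolimus in adult liver-transplant
recipients, built around routine therapeutic-drug-monitoring (TDM)
trough data.

Tacrolimus, the cornerstone immunosuppressant after liver
transplantation, has a narrow therapeutic window and shows apparently
nonlinear kinetics early after surgery. `tacropop` implements and
compares the two modelling strategies used to describe this:

- an **empirical Michaelis–Menten dose–trough model**, in which the
  total daily dose `DD` (mg/day) and the steady-state whole-blood
  trough `C0` (ng/mL) satisfy

  ```
  DD = Vm * C0 / (f * Km + C0),   f = 10 / min(POD, 10)
  ```

  with a time-varying, covariate-dependent Michaelis constant `Km`
  (postoperative day, hematocrit, total bilirubin, recipient CYP3A5
  genotype, triazole-antifungal co-therapy), and

- a **theory-based one-compartment plasma model** with first-order
  absorption (`Ka` fixed at 4.48 1/h), apparent plasma clearance and
  volume, and saturable erythrocyte binding linking plasma and whole
  blood: `Cwb = Cp + Cp * HCT * Bmax / (Cp + KD)` with `Bmax = 418`,
  `KD = 3.8` ug/L and hematocrit as a fraction.

Around the models the package provides, in plain tidyverse style
(tibbles in and out, `tidy()`/`glance()`/`autoplot()` methods):

- **FOCE-I estimation** (first-order conditional estimation with
  interaction) written from scratch: conditional-mode search, the
  linearized marginal likelihood, standard errors, shrinkage
  (`tac_fit()`, `foce_ofv()`, `conditional_eta_modes()`,
  `tac_shrinkage()`);
- **stepwise covariate selection** with the 3.84/6.63 likelihood-ratio
  thresholds and the 20%-effect relevance rule (`tac_stepwise()`);
- **diagnostics**: prediction-error metrics (MDPE/MAPE/F20/F30),
  nonparametric bootstrap, prediction- and variability-corrected visual
  predictive checks, and normalized prediction distribution errors with
  the Bonferroni global test (`tac_pred_errors()`, `tac_bootstrap()`,
  `tac_vpc()`, `tac_npde()`);
- a **synthetic TDM cohort generator** matched to the published cohort
  (covariate and genotype distributions, Cockcroft–Gault creatinine
  clearance, dose-titration course toward the 8–12 ng/mL target) with
  stored ground truth for simulation-estimation experiments
  (`simulate_cohort()`);
- a **Monte Carlo starting-dose engine** producing the 48-stratum
  (genotype x antifungal x hematocrit band x bilirubin band)
  recommendation table (`tac_dose_table()`).

The published model estimates ship as presets:
`tac_preset("mm_base")`, `"mm_final"`, `"theory_base"`,
`"theory_final"`.

## Worked example

Simulate a cohort from the final MM model and refit it:

```r
library(tacropop)

truth <- tac_preset("mm_final")
coh   <- simulate_cohort(176, truth, seed = 42)
fit   <- tac_fit(coh$observations, truth)
tidy(fit)
#> # A tibble: 10 × 7
#>    parameter              type      estimate     se rse_pct conf_low conf_high
#>    <chr>                  <chr>        <dbl>  <dbl>   <dbl>    <dbl>     <dbl>
#>  1 vm                     fixed        6.88  0.312     4.53    6.27      7.49
#>  2 km                     fixed        6.73  0.844    12.6     5.07      8.38
#>  3 beta_km_pod            covariate    0.301 0.0286    9.50    0.245     0.357
#>  4 beta_km_hct            covariate    1.67  0.251    15.0     1.18      2.16
#>  5 beta_km_tbil           covariate    0.413 0.0582   14.1     0.299     0.527
#>  6 beta_km_cyp3a5_carrier covariate   -0.316 0.0691   21.9    -0.451    -0.180
#>  7 beta_km_taf            covariate    2.36  0.352    14.9     1.67      3.05
#>  8 omega2_km              omega2       0.372 0.0531   14.3     0.268     0.476
#>  9 sigma_prop             sigma        0.235 0.0164    6.96    0.203     0.267
#> 10 sigma_add              sigma        0.499 0.0517   10.3     0.398     0.601
glance(fit)
#> # A tibble: 1 × 7
#>     ofv n_subjects n_obs n_parameters converged eps_shrinkage_pct
#>   <dbl>      <int> <int>        <int> <lgl>                 <dbl>
#> 1 2577.        176   881           10 TRUE                   7.97
#> # ℹ 1 more variable: max_eta_shrinkage_pct <dbl>
```

The estimates scatter around the generating values (`Vm` 6.62, `Km`
6.46, exponents 0.277/1.16/0.286, shifts -0.365/2.15, `omega_Km` 65.3%
CV, residual 20.4%/0.568) within one to two standard errors — the
sampling noise expected at a single 176-subject cohort. Diagnostics and
dosing run off the same objects:

```r
tac_pred_errors(fit)          # MDPE/MAPE/F20/F30 for PRED and IPRED
autoplot(tac_vpc(fit, n_sim = 500, seed = 1))
tac_npde(fit, seed = 1)       # global test of mean/variance/normality
tab <- tac_dose_table(tac_preset("mm_final"), seed = 1)
tidy(tab)                     # 48 strata, dose_low-dose_high in mg
autoplot(tab)                 # genotype x antifungal boxplot grid
```

The dose table reproduces the clinical orderings of the published
simulations: recommended starting doses fall with bilirubin band,
hematocrit band and antifungal co-therapy, rise for CYP3A5 expressers,
and stay below the saturation dose `Vm`.

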