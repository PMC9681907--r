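# Deterministic model mathematics: the MM dose-trough relation and its
# inverse, the steady-state one-compartment plasma trough, and the
# saturable whole-blood/plasma partition.

#' Predicted daily dose under the Michaelis-Menten model
#'
#' The MM model relates the total daily dose to the steady-state
#' whole-blood trough: `DD = Vm * C0 / (f * Km + C0)`.  `Km` is the trough
#' concentration at half the maximum dose rate.  When `time_factor` is on,
#' the effective Michaelis constant is inflated early after surgery by
#' `f = 10 / min(POD, 10)` (f = 1 from postoperative day 10 onward).
#'
#' @param vm Maximum steady-state daily dose rate (mg/day).
#' @param km Individual Michaelis constant (ng/mL), covariate-adjusted.
#' @param c0 Steady-state trough concentration (ng/mL).
#' @param pod Postoperative day; only used when `time_factor` is `TRUE`.
#' @param time_factor Apply the early-postoperative factor.
#' @return Predicted daily dose (mg/day); always strictly below `vm`.
#' @examples
#' mm_dose_pred(6.62, 6.46, 6.46)  # half-maximum: Vm / 2
#' @export
mm_dose_pred <- function(vm, km, c0, pod = NULL, time_factor = FALSE) {
  if (any(vm <= 0) || any(km <= 0) || any(c0 <= 0)) {
    abort("`vm`, `km` and `c0` must be positive.")
  }
  f <- mm_time_factor(pod, time_factor)
  vm * c0 / (f * km + c0)
}

mm_time_factor <- function(pod, time_factor) {
  if (!isTRUE(time_factor)) return(1)
  if (is.null(pod)) abort("`pod` is required when the time factor is on.")
  if (any(pod <= 0)) abort("`pod` must be positive.")
  10 / pmin(pod, 10)
}

#' Steady-state trough implied by a daily dose (inverse MM relation)
#'
#' Algebraic inverse of [mm_dose_pred()]:
#' `C0 = f * Km * DD / (Vm - DD)`.  Doses at or above `Vm` have no
#' steady state (the accumulation regime) and raise an error.
#'
#' @inheritParams mm_dose_pred
#' @param dd Daily dose (mg/day), strictly between 0 and `vm`.
#' @return Steady-state trough concentration (ng/mL).
#' @export
mm_c0_solve <- function(vm, km, dd, pod = NULL, time_factor = FALSE) {
  if (any(dd <= 0)) abort("`dd` must be positive.")
  if (any(dd >= vm)) {
    abort("Daily dose at or above Vm: no steady state (drug accumulation).")
  }
  f <- mm_time_factor(pod, time_factor)
  f * km * dd / (vm - dd)
}

#' Whole-blood concentration from plasma concentration
#'
#' Saturable binding of tacrolimus to erythrocytes:
#' `Cwb = Cp + Cp * HCT * Bmax / (Cp + KD)`, with hematocrit as a
#' fraction.  At vanishing plasma concentration the blood:plasma ratio
#' approaches `1 + HCT * Bmax / KD` (about 39.5 at HCT 0.35).
#'
#' @param cp Plasma concentration (ng/mL).
#' @param hct Hematocrit as a fraction in `[0, 1)`.
#' @param partition [partition_constants()].
#' @return Whole-blood concentration (ng/mL).
#' @export
plasma_to_blood <- function(cp, hct, partition = partition_constants()) {
  if (any(cp < 0)) abort("`cp` must be non-negative.")
  if (any(hct < 0 | hct >= 1)) {
    abort("`hct` must be a fraction in [0, 1); divide percent by 100.")
  }
  cp + cp * hct * partition$b_max / (cp + partition$k_d)
}

#' Plasma concentration from whole-blood concentration
#'
#' Inverts [plasma_to_blood()] by solving the quadratic
#' `Cp^2 + Cp * (KD + HCT * Bmax - Cwb) - KD * Cwb = 0` for its unique
#' non-negative root.
#'
#' @param cwb Whole-blood concentration (ng/mL).
#' @inheritParams plasma_to_blood
#' @return Plasma concentration (ng/mL).
#' @export
blood_to_plasma <- function(cwb, hct, partition = partition_constants()) {
  if (any(cwb < 0)) abort("`cwb` must be non-negative.")
  if (any(hct < 0 | hct >= 1)) {
    abort("`hct` must be a fraction in [0, 1); divide percent by 100.")
  }
  b <- partition$k_d + hct * partition$b_max - cwb
  (-b + sqrt(b^2 + 4 * partition$k_d * cwb)) / 2
}

#' Steady-state trough of a one-compartment oral model
#'
#' Closed-form steady-state concentration for repeated first-order oral
#' dosing at interval `tau_h`, sampled `tad_h` hours after a dose:
#' \deqn{C = \frac{D}{V}\,\frac{k_a}{k_a-k_e}\left[
#'   \frac{e^{-k_e t}}{1-e^{-k_e \tau}} -
#'   \frac{e^{-k_a t}}{1-e^{-k_a \tau}}\right],\quad k_e = CL/V.}
#' Doses are in mg and volumes in L, so the result is in ug/L = ng/mL.
#' The removable singularity at `ka = ke` is handled by a small relative
#' offset of `ka`.
#'
#' @param cl Apparent clearance (L/h).
#' @param v Apparent distribution volume (L).
#' @param ka First-order absorption rate constant (1/h).
#' @param dose_mg Per-interval dose (mg).
#' @param tau_h Dosing interval (h).
#' @param tad_h Time after dose (h).
#' @return Concentration (ng/mL).
#' @export
ss_trough_plasma <- function(cl, v, ka, dose_mg, tau_h = 12, tad_h = 12) {
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0)) {
    abort("`cl`, `v` and `ka` must be positive.")
  }
  if (any(dose_mg < 0)) abort("`dose_mg` must be non-negative.")
  ke <- cl / v
  near <- abs(ka - ke) < 1e-8 * ke
  if (any(near)) ka <- ifelse(near, ke * (1 + 1e-6), ka)
  amt <- dose_mg * 1000 # mg -> ug, with V in L gives ug/L = ng/mL
  (amt / v) * (ka / (ka - ke)) *
    (exp(-ke * tad_h) / (1 - exp(-ke * tau_h)) -
       exp(-ka * tad_h) / (1 - exp(-ka * tau_h)))
}

#' Individual structural parameter value
#'
#' Composes a typical value with covariate effects and the exponential
#' between-subject random effect: additive (linear-form) shifts are summed
#' onto the typical value, multiplicative factors and `exp(eta)` are then
#' applied.
#'
#' @param tv Typical value (positive).
#' @param effects List of [covariate_effect()] objects acting on this
#'   parameter.
#' @param covariates Named list or one-row data frame of covariate values.
#' @param eta Random-effect value.
#' @return Individual parameter value.
#' @export
individual_param <- function(tv, effects = list(), covariates = list(),
                             eta = 0) {
  if (any(tv <= 0)) abort("`tv` must be positive.")
  add <- 0
  mult <- 1
  for (ce in effects) {
    val <- covariates[[ce$covariate]]
    if (is.null(val)) abort(paste0("Missing covariate: ", ce$covariate))
    fac <- covariate_factor(ce, val)
    if (ce$form == "linear") add <- add + fac else mult <- mult * fac
  }
  (tv + add) * mult * exp(eta)
}

#' Residual variance of the observation model
#'
#' Combined error `Y = F + F*eps1 + eps2` gives
#' `Var(Y) = F^2 * sigma_prop^2 + sigma_add^2`; the proportional and
#' additive models are the obvious special cases.
#'
#' @param f Model prediction(s).
#' @param sigma_prop,sigma_add Residual standard deviations.
#' @return Variance of the observation around `f`.
#' @export
residual_variance <- function(f, sigma_prop, sigma_add = 0) {
  f^2 * sigma_prop^2 + sigma_add^2
}

# --- vectorized per-row typical values -----------------------------------

# Per-row typical value of `param` under `spec`, given a data frame of
# observation rows. Applies all covariate effects (not eta, not the time
# factor).
typical_param_rows <- function(spec, param, data) {
  tv <- spec$fixed[[param]]
  add <- 0
  mult <- rep(1, nrow(data))
  for (ce in spec$covariates) {
    if (ce$parameter != param) next
    val <- data[[ce$covariate]]
    if (is.null(val)) {
      abort(paste0("Dataset lacks covariate column: ", ce$covariate))
    }
    fac <- covariate_factor(ce, val)
    if (ce$form == "linear") add <- add + fac else mult <- mult * fac
  }
  (tv + add) * mult
}

# Prediction function factory.  Returns function(eta_mat) -> per-row
# predictions, where eta_mat is n_subject x n_eta (columns in
# spec_eta_params() order) and `subj` maps rows to subjects.
make_predfun <- function(spec, data, subj) {
  eta_par <- spec_eta_params(spec)
  col_of <- function(p) {
    i <- match(p, eta_par)
    if (is.na(i)) NULL else i
  }
  if (spec$model == "mm") {
    km_typ <- typical_param_rows(spec, "km", data)
    vm_typ <- typical_param_rows(spec, "vm", data)
    f_time <- mm_time_factor(data$pod, spec$time_factor)
    eff_km <- f_time * km_typ
    c0 <- data$c0
    i_km <- col_of("km")
    i_vm <- col_of("vm")
    function(eta_mat) {
      km_i <- if (is.null(i_km)) eff_km else eff_km * exp(eta_mat[subj, i_km])
      vm_i <- if (is.null(i_vm)) vm_typ else vm_typ * exp(eta_mat[subj, i_vm])
      vm_i * c0 / (km_i + c0)
    }
  } else {
    cl_typ <- typical_param_rows(spec, "cl", data)
    v_typ <- typical_param_rows(spec, "v", data)
    ka <- spec$fixed[["ka"]]
    dose <- data$daily_dose / 2 # daily dose split q12h
    hct_fr <- data$hct / 100
    part <- spec$partition
    i_cl <- col_of("cl")
    i_v <- col_of("v")
    function(eta_mat) {
      cl_i <- if (is.null(i_cl)) cl_typ else cl_typ * exp(eta_mat[subj, i_cl])
      v_i <- if (is.null(i_v)) v_typ else v_typ * exp(eta_mat[subj, i_v])
      cp <- ss_trough_plasma(cl_i, v_i, ka, dose, tau_h = 12, tad_h = 12)
      plasma_to_blood(cp, hct_fr, part)
    }
  }
}

#' Whole-blood trough predicted by the theory-based model
#'
#' Builds the individual clearance and volume from the specification's
#' covariate effects and random effects, computes the steady-state plasma
#' trough for the daily dose split into two 12-hourly doses (sampled 12 h
#' after a dose), and converts to whole blood with the row's hematocrit.
#'
#' @param spec A theory-model [tac_spec()].
#' @param data Observation rows with `daily_dose`, `hct` (percent) and any
#'   covariate columns the model needs.
#' @param eta Matrix (`n_subjects` by number of random effects) or a single
#'   row; defaults to zero.
#' @param subject Integer subject index per row of `data`.
#' @return Predicted whole-blood trough(s), ng/mL.
#' @export
theory_pred_cwb <- function(spec, data, eta = NULL, subject = NULL) {
  stopifnot(spec$model == "theory")
  n_eta <- length(spec_eta_params(spec))
  if (is.null(subject)) subject <- rep(1L, nrow(data))
  if (is.null(eta)) eta <- matrix(0, max(subject), max(n_eta, 1))
  if (is.vector(eta)) eta <- matrix(eta, nrow = 1)
  make_predfun(spec, data, subject)(eta)
}

#' Population (typical) prediction for a dataset
#'
#' Model prediction at zero random effects for every row of `data`.
#'
#' @param spec A [tac_spec()].
#' @param data Observation rows.
#' @return Numeric vector of predictions (MM: daily dose mg/day; theory:
#'   whole-blood trough ng/mL).
#' @export
population_pred <- function(spec, data) {
  n <- nrow(data)
  subj <- rep(1L, n)
  eta <- matrix(0, 1, max(length(spec_eta_params(spec)), 1))
  make_predfun(spec, data, subj)(eta)
}
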