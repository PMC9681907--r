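# Model specifications: structural model choice, covariate effects,
# between-subject variability and residual error.

#' Describe a covariate effect on a structural parameter
#'
#' A covariate effect modifies the typical value of a structural parameter.
#' Continuous covariates are normalized to a reference value (the population
#' median) and entered as power, exponential or linear terms; binary or
#' allele-count covariates use a proportional-shift ("scale") term; a
#' saturable Emax term is available for the daily-dose effect on clearance.
#'
#' Functional forms, with `x` the covariate value, `ref` the reference and
#' `theta` the coefficient(s):
#' \describe{
#'   \item{power}{multiplier `(x / ref) ^ theta`}
#'   \item{exponential}{multiplier `exp(theta * x / ref)`}
#'   \item{linear}{additive shift `theta * x / ref` on the typical value}
#'   \item{scale}{multiplier `1 + theta * x`, for covariates coded 0/1
#'     (or allele counts 0/1/2)}
#'   \item{emax}{multiplier `theta[1] * x / (theta[2] + x)`; `theta` must be
#'     `c(emax = ..., e50 = ...)`}
#' }
#'
#' @param parameter Name of the structural parameter the effect acts on
#'   (e.g. `"km"`, `"cl"`).
#' @param covariate Name of the covariate column in the dataset.
#' @param form One of `"power"`, `"exponential"`, `"linear"`, `"scale"`,
#'   `"emax"`.
#' @param theta Coefficient(s); length 2 for `"emax"`, length 1 otherwise.
#' @param reference Covariate normalizer (population median); must be
#'   positive for continuous forms. Ignored by `"scale"` and `"emax"`.
#' @return An object of class `tac_covariate`.
#' @examples
#' covariate_effect("km", "hct", "power", theta = 1.16, reference = 31)
#' @export
covariate_effect <- function(parameter, covariate,
                             form = c("power", "exponential", "linear",
                                      "scale", "emax"),
                             theta, reference = 1) {
  form <- match.arg(form)
  if (form == "emax") {
    if (length(theta) != 2) {
      abort("`theta` must have length 2 (emax, e50) for the emax form.")
    }
    theta <- setNames(as.numeric(theta), c("emax", "e50"))
  } else {
    if (length(theta) != 1) abort("`theta` must be a single coefficient.")
    theta <- as.numeric(theta)
  }
  if (form %in% c("power", "exponential", "linear") && reference <= 0) {
    abort("`reference` must be positive for continuous covariate forms.")
  }
  structure(
    list(parameter = parameter, covariate = covariate, form = form,
         theta = theta, reference = reference),
    class = "tac_covariate"
  )
}

#' Evaluate a covariate effect
#'
#' Returns the multiplier (or, for the linear form, the additive shift)
#' contributed by one covariate effect at the given covariate value(s).
#'
#' @param effect A [covariate_effect()].
#' @param value Covariate value(s).
#' @return Numeric vector the same length as `value`.
#' @examples
#' eff <- covariate_effect("km", "taf", "scale", theta = 2.15)
#' covariate_factor(eff, c(0, 1))
#' @export
covariate_factor <- function(effect, value) {
  stopifnot(inherits(effect, "tac_covariate"))
  switch(effect$form,
    power = {
      if (any(value <= 0)) {
        abort("Power-form covariate values must be positive.")
      }
      (value / effect$reference)^effect$theta
    },
    exponential = exp(effect$theta * value / effect$reference),
    linear = effect$theta * value / effect$reference,
    scale = 1 + effect$theta * value,
    emax = effect$theta[["emax"]] * value / (effect$theta[["e50"]] + value)
  )
}

#' Construct a population pharmacokinetic model specification
#'
#' A `tac_spec` bundles everything that defines one candidate model: the
#' structural model (`"mm"` for the Michaelis-Menten dose-trough model,
#' `"theory"` for the one-compartment plasma model with saturable
#' erythrocyte binding), its fixed effects, covariate effects,
#' between-subject variance terms and the residual-error model.
#'
#' Between-subject variability enters exponentially,
#' `P_i = TV(P) * exp(eta_i)` with `eta_i ~ N(0, omega^2)`; an `omega2`
#' entry of 0 fixes the corresponding random effect to zero.  The residual
#' model is combined, `Y = F + F*eps1 + eps2`; set `sigma_add = 0` for a
#' purely proportional model or `sigma_prop = 0` for additive.
#'
#' For the MM model the dependent variable is the daily dose predicted from
#' the observed trough, `DD = Vm * C0 / (f * Km_i + C0)`, where the early
#' postoperative time factor `f = 10 / min(POD, 10)` applies when
#' `time_factor = TRUE`.  For the theory-based model the dependent variable
#' is the whole-blood trough predicted from the plasma one-compartment
#' model and the hematocrit-dependent partition.
#'
#' @param model `"mm"` or `"theory"`.
#' @param fixed Named numeric vector of fixed effects. MM: `vm` (mg/day)
#'   and `km` (ng/mL). Theory: `cl` (L/h), `v` (L) and `ka` (1/h; never
#'   estimated).
#' @param covariates List of [covariate_effect()] objects.
#' @param omega2 Named numeric vector of between-subject variances, keyed
#'   by structural parameter name.
#' @param sigma_prop,sigma_add Residual standard deviations (proportional
#'   as a fraction, additive in units of the dependent variable).
#' @param time_factor Logical; include the `10/min(POD, 10)` factor on the
#'   effective Michaelis constant (MM model only).
#' @param partition [partition_constants()] used by the theory model.
#' @return An object of class `tac_spec`.
#' @seealso [tac_preset()] for the published model presets.
#' @export
tac_spec <- function(model = c("mm", "theory"), fixed, covariates = list(),
                     omega2 = numeric(), sigma_prop = 0, sigma_add = 0,
                     time_factor = FALSE,
                     partition = partition_constants()) {
  model <- match.arg(model)
  need <- if (model == "mm") c("vm", "km") else c("cl", "v", "ka")
  if (!all(need %in% names(fixed))) {
    abort(paste0("`fixed` must contain: ", paste(need, collapse = ", ")))
  }
  if (any(fixed[need] <= 0)) abort("All fixed effects must be positive.")
  if (any(omega2 < 0)) abort("`omega2` entries must be non-negative.")
  if (sigma_prop < 0 || sigma_add < 0) {
    abort("Residual standard deviations must be non-negative.")
  }
  if (sigma_prop == 0 && sigma_add == 0) {
    abort("At least one residual component must be positive.")
  }
  ok_par <- if (model == "mm") c("vm", "km") else c("cl", "v")
  bad <- setdiff(names(omega2), ok_par)
  if (length(bad)) abort(paste0("Unknown omega2 parameter: ", bad[1]))
  for (ce in covariates) {
    if (!inherits(ce, "tac_covariate")) {
      abort("`covariates` must be a list of covariate_effect() objects.")
    }
    if (!ce$parameter %in% ok_par) {
      abort(paste0("Covariate targets unknown parameter: ", ce$parameter))
    }
  }
  structure(
    list(model = model, fixed = fixed, covariates = covariates,
         omega2 = omega2, sigma_prop = sigma_prop, sigma_add = sigma_add,
         time_factor = isTRUE(time_factor), partition = partition),
    class = "tac_spec"
  )
}

#' Erythrocyte-binding partition constants
#'
#' Maximum binding capacity of red cells (`b_max`) and dissociation
#' constant (`k_d`) of the saturable whole-blood/plasma partition, both in
#' ug/L (equivalently ng/mL).
#'
#' @param b_max Maximum bound concentration per unit red-cell volume.
#' @param k_d Dissociation equilibrium constant.
#' @export
partition_constants <- function(b_max = 418, k_d = 3.8) {
  if (b_max <= 0 || k_d <= 0) abort("Partition constants must be positive.")
  list(b_max = b_max, k_d = k_d)
}

#' Published model presets
#'
#' Returns a [tac_spec()] populated with the reported population estimates
#' for one of the four models: the covariate-free and final versions of the
#' Michaelis-Menten dose-trough model (`"mm_base"`, `"mm_final"`) and of
#' the theory-based one-compartment plasma model (`"theory_base"`,
#' `"theory_final"`).  These presets are used as simulation ground truth
#' throughout the package.
#'
#' @param name One of `"mm_base"`, `"mm_final"`, `"theory_base"`,
#'   `"theory_final"`.
#' @return A `tac_spec`.
#' @examples
#' tac_preset("mm_final")
#' @export
tac_preset <- function(name = c("mm_base", "mm_final", "theory_base",
                                "theory_final")) {
  name <- match.arg(name)
  switch(name,
    mm_base = tac_spec(
      model = "mm",
      fixed = c(vm = 6.1, km = 6.19),
      omega2 = c(km = 0.748^2),
      sigma_prop = 0.29, sigma_add = 0.48,
      time_factor = FALSE
    ),
    mm_final = tac_spec(
      model = "mm",
      fixed = c(vm = 6.62, km = 6.46),
      covariates = list(
        covariate_effect("km", "pod", "power", theta = 0.277,
                         reference = 15),
        covariate_effect("km", "hct", "power", theta = 1.16,
                         reference = 31),
        covariate_effect("km", "tbil", "power", theta = 0.286,
                         reference = 58.25),
        covariate_effect("km", "cyp3a5_carrier", "scale", theta = -0.365),
        covariate_effect("km", "taf", "scale", theta = 2.15)
      ),
      omega2 = c(km = 0.653^2),
      sigma_prop = 0.204, sigma_add = 0.568,
      time_factor = TRUE
    ),
    theory_base = tac_spec(
      model = "theory",
      fixed = c(cl = 456, v = 10700, ka = 4.48),
      omega2 = c(cl = 0.422^2, v = 0.644^2),
      sigma_prop = 0.143
    ),
    theory_final = tac_spec(
      model = "theory",
      fixed = c(cl = 234, v = 11000, ka = 4.48),
      covariates = list(
        covariate_effect("cl", "ast", "power", theta = -0.216,
                         reference = 45),
        covariate_effect("cl", "daily_dose", "emax",
                         theta = c(emax = 3.51, e50 = 2.44)),
        covariate_effect("cl", "cyp3a5_carrier", "scale", theta = 0.168),
        covariate_effect("cl", "taf", "scale", theta = -0.575),
        covariate_effect("v", "pod", "exponential", theta = 0.887,
                         reference = 15)
      ),
      omega2 = c(cl = 0.297^2, v = 0.592^2),
      sigma_prop = 0.308
    )
  )
}

#' @export
print.tac_spec <- function(x, ...) {
  cat("<tac_spec> ", if (x$model == "mm") {
    "Michaelis-Menten dose-trough model"
  } else {
    "theory-based one-compartment plasma model"
  }, "\n", sep = "")
  cat("  fixed effects: ",
      paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  if (length(x$covariates)) {
    for (ce in x$covariates) {
      cat("  covariate: ", ce$covariate, " on ", ce$parameter, " (",
          ce$form, ", theta = ",
          paste(signif(ce$theta, 4), collapse = "/"), ")\n", sep = "")
    }
  }
  if (length(x$omega2)) {
    cat("  BSV (CV%): ",
        paste(names(x$omega2), signif(100 * sqrt(x$omega2), 3),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  cat("  residual: prop ", signif(x$sigma_prop, 3), ", add ",
      signif(x$sigma_add, 3), "\n", sep = "")
  if (x$model == "mm") {
    cat("  early-POD time factor: ",
        if (x$time_factor) "on" else "off", "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a model specification to YAML
#'
#' @param spec A [tac_spec()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "tac_spec"))
  obj <- list(
    model = spec$model,
    fixed = as.list(spec$fixed),
    covariates = lapply(spec$covariates, function(ce) {
      list(parameter = ce$parameter, covariate = ce$covariate,
           form = ce$form, theta = as.list(ce$theta),
           reference = ce$reference)
    }),
    omega2 = as.list(spec$omega2),
    sigma_prop = spec$sigma_prop,
    sigma_add = spec$sigma_add,
    time_factor = spec$time_factor,
    partition = spec$partition
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path File written by [write_spec()].
#' @return A [tac_spec()].
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- lapply(obj$covariates, function(ce) {
    covariate_effect(ce$parameter, ce$covariate, ce$form,
                     theta = unlist(ce$theta), reference = ce$reference)
  })
  tac_spec(
    model = obj$model,
    fixed = unlist(obj$fixed),
    covariates = covs,
    omega2 = if (length(obj$omega2)) unlist(obj$omega2) else numeric(),
    sigma_prop = obj$sigma_prop,
    sigma_add = obj$sigma_add,
    time_factor = obj$time_factor,
    partition = partition_constants(obj$partition$b_max, obj$partition$k_d)
  )
}

# Parameters carrying between-subject variability, in a stable order.
spec_eta_params <- function(spec) {
  names(spec$omega2)[spec$omega2 > 0]
}
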