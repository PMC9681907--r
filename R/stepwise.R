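# Stepwise covariate selection: forward inclusion at a likelihood-ratio
# drop of 3.84 (p < 0.05, 1 df), backward elimination at a rise of 6.63
# (p < 0.01, 1 df), plus the clinical-relevance rule that an effect must
# change its parameter by at least 20% across the observed covariate
# range.

#' Candidate covariate table
#'
#' Convenience constructor for the candidate list consumed by
#' [tac_stepwise()].
#'
#' @param parameter,covariate,form,reference Vectors defining one
#'   candidate [covariate_effect()] per element (recycled as usual).
#' @param init Starting coefficient for each candidate.
#' @return Tibble of candidates.
#' @export
stepwise_candidates <- function(parameter, covariate, form,
                                reference = 1, init = 0.1) {
  tibble::tibble(parameter = parameter, covariate = covariate,
                 form = form, reference = reference, init = init)
}

# Relative change of the parameter across the observed covariate range.
# Effects below 20% are considered clinically irrelevant.
effect_magnitude <- function(effect, values) {
  values <- values[is.finite(values)]
  if (effect$form == "linear") {
    # additive on the typical value: needs the typical value for scale,
    # use the shift range relative to the reference shift
    rng <- range(covariate_factor(effect, values))
    return(abs(rng[2] - rng[1]))
  }
  fac <- covariate_factor(effect, unique(range(values)))
  max(fac) / min(fac) - 1
}

#' Stepwise covariate model building
#'
#' Forward phase: each remaining candidate is added to the current model
#' and refitted; the candidate with the largest objective-function drop
#' is included if the drop reaches `forward_dofv` (ties broken by
#' declaration order).  Candidates whose fitted effect changes the
#' parameter by less than `min_effect` across the observed covariate
#' range are not retained regardless of the drop.  Backward phase:
#' included covariates whose removal raises the objective by less than
#' `backward_dofv` are eliminated, least supported first.
#'
#' @param data Observation rows.
#' @param base_spec Base-model [tac_spec()] (starting values for its
#'   parameters).
#' @param candidates Tibble from [stepwise_candidates()].
#' @param forward_dofv Required OFV drop for inclusion (3.84 = chi-square
#'   0.05, 1 df).
#' @param backward_dofv Required OFV rise for retention (6.63 =
#'   chi-square 0.01, 1 df).
#' @param min_effect Minimum relative parameter change across the
#'   observed covariate range (0.2 = 20%).
#' @param control Passed to [tac_fit()].
#' @return A `tac_stepwise` object: `$final_fit`, `$final_spec`, and
#'   `$steps`, a log with one row per candidate evaluation.
#' @export
tac_stepwise <- function(data, base_spec, candidates,
                         forward_dofv = 3.84, backward_dofv = 6.63,
                         min_effect = 0.20, control = list()) {
  # candidate fits keep the ridge-polish stage: a stalled candidate fit
  # understates its OFV drop and can silently reject a true covariate
  control <- modifyList(list(polish = TRUE), control)
  fit_quiet <- function(spec) {
    tryCatch(tac_fit(data, spec, estimate_se = FALSE, control = control),
             error = function(e) NULL)
  }
  add_candidate <- function(spec, cand, theta) {
    spec$covariates <- c(spec$covariates, list(covariate_effect(
      cand$parameter, cand$covariate, cand$form,
      theta = theta, reference = cand$reference)))
    spec
  }
  current <- fit_quiet(base_spec)
  if (is.null(current)) abort("Base model fit failed.")
  steps <- list()
  log_step <- function(phase, cand, dofv, magnitude, decision) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      phase = phase, parameter = cand$parameter,
      covariate = cand$covariate, form = cand$form,
      delta_ofv = dofv, effect_magnitude = magnitude,
      decision = decision)
  }

  remaining <- candidates
  included <- candidates[0, ]
  # forward inclusion
  repeat {
    if (!nrow(remaining)) break
    best <- NULL
    results <- vector("list", nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      cand <- remaining[i, ]
      spec_i <- add_candidate(current$spec, cand, cand$init)
      fit_i <- fit_quiet(spec_i)
      if (is.null(fit_i)) {
        log_step("forward", cand, NA_real_, NA_real_, "fit_failed")
        next
      }
      dofv <- current$ofv - fit_i$ofv
      eff <- fit_i$spec$covariates[[length(fit_i$spec$covariates)]]
      mag <- effect_magnitude(eff, data[[cand$covariate]])
      results[[i]] <- list(cand = cand, fit = fit_i, dofv = dofv,
                           mag = mag)
      if (dofv >= forward_dofv && mag < min_effect) {
        log_step("forward", cand, dofv, mag, "rejected_small_effect")
        results[[i]] <- NULL
      }
    }
    qualifying <- purrr::keep(results, ~ !is.null(.x) &&
                                .x$dofv >= forward_dofv)
    if (!length(qualifying)) {
      for (r in purrr::compact(results)) {
        log_step("forward", r$cand, r$dofv, r$mag, "rejected")
      }
      break
    }
    dofvs <- vapply(qualifying, function(r) r$dofv, numeric(1))
    best <- qualifying[[which.max(dofvs)]]
    for (r in purrr::compact(results)) {
      same <- identical(r$cand, best$cand)
      if (!same) log_step("forward", r$cand, r$dofv, r$mag, "rejected")
    }
    log_step("forward", best$cand, best$dofv, best$mag, "included")
    current <- best$fit
    included <- dplyr::bind_rows(included, best$cand)
    keep <- !(remaining$parameter == best$cand$parameter &
                remaining$covariate == best$cand$covariate &
                remaining$form == best$cand$form)
    remaining <- remaining[keep, ]
  }

  # backward elimination
  repeat {
    if (!nrow(included)) break
    worst <- NULL
    worst_rise <- Inf
    worst_fit <- NULL
    for (i in seq_len(nrow(included))) {
      cand <- included[i, ]
      spec_i <- current$spec
      drop_idx <- which(vapply(spec_i$covariates, function(ce) {
        ce$parameter == cand$parameter && ce$covariate == cand$covariate &&
          ce$form == cand$form
      }, logical(1)))[1]
      spec_i$covariates <- spec_i$covariates[-drop_idx]
      fit_i <- fit_quiet(spec_i)
      if (is.null(fit_i)) next
      rise <- fit_i$ofv - current$ofv
      if (rise < worst_rise) {
        worst <- i
        worst_rise <- rise
        worst_fit <- fit_i
      }
    }
    if (is.null(worst) || worst_rise >= backward_dofv) {
      for (i in seq_len(nrow(included))) {
        log_step("backward", included[i, ], NA_real_, NA_real_,
                 "retained")
      }
      break
    }
    log_step("backward", included[worst, ], worst_rise, NA_real_,
             "removed")
    included <- included[-worst, ]
    current <- worst_fit
  }

  structure(list(final_fit = current, final_spec = current$spec,
                 steps = dplyr::bind_rows(steps)),
            class = "tac_stepwise")
}

#' @export
tidy.tac_stepwise <- function(x, ...) x$steps

#' @export
print.tac_stepwise <- function(x, ...) {
  inc <- x$steps[x$steps$decision == "included", ]
  cat("<tac_stepwise> ", nrow(inc), " covariate(s) included\n", sep = "")
  print(as.data.frame(x$steps), digits = 4)
  invisible(x)
}
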