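# Monte Carlo starting-dose recommendation under the final MM model:
# stratified by recipient CYP3A5 genotype, triazole-antifungal co-therapy,
# hematocrit band and total-bilirubin band, evaluated on postoperative
# day 7 against the early target trough window of 8-12 ng/mL.

#' Dosing simulation scenario grid
#'
#' The 48 strata of the starting-dose table: recipient CYP3A5 genotype
#' group (expresser = at least one *1 allele) x triazole-antifungal
#' co-therapy x hematocrit band (20-30, 30-40, 40-50%) x total-bilirubin
#' band (<17.1, 17.1-85.5, 85.5-171, >=171 umol/L; the open bands are
#' bounded at 5.1 and 300 for sampling).
#'
#' @param pod Postoperative day at evaluation.
#' @param target Target trough window (ng/mL).
#' @return Tibble of scenarios.
#' @export
dose_scenarios <- function(pod = 7, target = c(8, 12)) {
  tidyr::expand_grid(
    genotype = c("CYP3A5*1 carrier", "CYP3A5*3/*3"),
    taf = c(1L, 0L),
    hct_band = c("20-30", "30-40", "40-50"),
    tbil_band = c("<17.1", "17.1-85.5", "85.5-171", ">=171")
  ) %>%
    mutate(
      cyp3a5_carrier = as.integer(.data$genotype == "CYP3A5*1 carrier"),
      hct_lo = c("20-30" = 20, "30-40" = 30,
                 "40-50" = 40)[.data$hct_band],
      hct_hi = c("20-30" = 30, "30-40" = 40,
                 "40-50" = 50)[.data$hct_band],
      tbil_lo = c("<17.1" = 5.1, "17.1-85.5" = 17.1, "85.5-171" = 85.5,
                  ">=171" = 171)[.data$tbil_band],
      tbil_hi = c("<17.1" = 17.1, "17.1-85.5" = 85.5, "85.5-171" = 171,
                  ">=171" = 300)[.data$tbil_band],
      pod = pod, target_lo = target[1], target_hi = target[2]
    )
}

# effective Michaelis constant for given covariate values (eta = 0 unless
# supplied), including the early-postoperative factor when enabled
scenario_km <- function(spec, hct, tbil, carrier, taf, pod, eta = 0) {
  row <- tibble::tibble(pod = pod, hct = hct, tbil = tbil,
                        cyp3a5_carrier = carrier, taf = taf)
  typical_param_rows(spec, "km", row) *
    mm_time_factor(pod, spec$time_factor) * exp(eta)
}

#' Typical steady-state trough for a dose in a scenario
#'
#' Deterministic (zero random effect) steady-state trough implied by a
#' daily dose at the scenario's covariate values, evaluated at both edges
#' of the hematocrit and bilirubin bands.
#'
#' @param spec Final MM-model [tac_spec()].
#' @param scenario One row of [dose_scenarios()].
#' @param dd Daily dose (mg/day), below the model's `vm`.
#' @return Tibble with the trough at the low and high band edges.
#' @export
typical_c0_for_dose <- function(spec, scenario, dd) {
  stopifnot(spec$model == "mm")
  vm <- spec$fixed[["vm"]]
  km_lo <- scenario_km(spec, scenario$hct_lo, scenario$tbil_lo,
                       scenario$cyp3a5_carrier, scenario$taf,
                       scenario$pod)
  km_hi <- scenario_km(spec, scenario$hct_hi, scenario$tbil_hi,
                       scenario$cyp3a5_carrier, scenario$taf,
                       scenario$pod)
  tibble::tibble(
    daily_dose = dd,
    c0_band_low = mm_c0_solve(vm, km_lo, dd),
    c0_band_high = mm_c0_solve(vm, km_hi, dd)
  )
}

#' Monte Carlo starting-dose table
#'
#' For each scenario, simulates subjects with hematocrit and bilirubin
#' drawn uniformly within the band and the Michaelis-constant random
#' effect drawn from the model, computes each subject's required daily
#' dose as the smallest dose-grid multiple whose steady-state trough
#' falls inside the target window, and reports the 2.5th-97.5th
#' percentile range of required doses rounded outward to the grid.
#'
#' @param spec Final MM-model [tac_spec()] (with `omega2` and residual
#'   components).
#' @param scenarios Tibble from [dose_scenarios()].
#' @param n_sim Simulated subjects per scenario.
#' @param dose_grid Dose grid step (mg).
#' @param seed RNG seed.
#' @return A `tac_dose_table`: `$table` has one row per scenario with
#'   `dose_low`, `dose_high`, the median required dose and the fraction
#'   of subjects with no feasible grid dose; per-subject dose draws are
#'   kept in the `doses` list column.
#' @export
tac_dose_table <- function(spec, scenarios = dose_scenarios(),
                           n_sim = 200, dose_grid = 0.25, seed = NULL) {
  stopifnot(spec$model == "mm")
  if (!is.null(seed)) set.seed(seed)
  vm <- spec$fixed[["vm"]]
  om <- sqrt(spec$omega2[["km"]] %||% 0)
  rows <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    hct <- runif(n_sim, sc$hct_lo, sc$hct_hi)
    tbil <- runif(n_sim, sc$tbil_lo, sc$tbil_hi)
    eta <- rnorm(n_sim, 0, om)
    km_i <- scenario_km(spec, hct, tbil, sc$cyp3a5_carrier, sc$taf,
                        sc$pod, eta)
    # dose window achieving the trough target, then the smallest grid dose
    d_lo <- vm * sc$target_lo / (km_i + sc$target_lo)
    d_hi <- vm * sc$target_hi / (km_i + sc$target_hi)
    d_grid <- ceiling(d_lo / dose_grid) * dose_grid
    feasible <- d_grid <= d_hi & d_grid < vm
    # no grid point inside the window: nearest grid dose to the window
    d_grid[!feasible & d_grid < vm] <-
      round(d_hi[!feasible & d_grid < vm] / dose_grid) * dose_grid
    usable <- d_grid > 0 & d_grid < vm
    doses <- d_grid[usable]
    qs <- quantile(doses, c(0.025, 0.5, 0.975))
    rows[[i]] <- sc %>%
      mutate(
        dose_low = floor(qs[[1]] / dose_grid) * dose_grid,
        dose_median = qs[[2]],
        dose_high = ceiling(qs[[3]] / dose_grid) * dose_grid,
        frac_infeasible = 1 - mean(feasible),
        flagged = mean(feasible) < 0.5,
        doses = list(doses)
      )
  }
  tab <- dplyr::bind_rows(rows)
  if (any(tab$flagged)) {
    warn("Some scenarios have no feasible grid dose for most subjects.")
  }
  structure(list(table = tab, n_sim = n_sim, dose_grid = dose_grid),
            class = "tac_dose_table")
}

#' @export
tidy.tac_dose_table <- function(x, ...) {
  select(x$table, -"doses")
}

#' @export
print.tac_dose_table <- function(x, ...) {
  cat("<tac_dose_table> ", nrow(x$table), " scenarios, ", x$n_sim,
      " simulated subjects each\n", sep = "")
  print(as.data.frame(tidy(x)), digits = 3)
  invisible(x)
}

#' @export
autoplot.tac_dose_table <- function(object, ...) {
  d <- tidyr::unnest(object$table, "doses")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tbil_band, y = .data$doses,
                                  fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$taf),
      cols = ggplot2::vars(.data$hct_band),
      labeller = ggplot2::labeller(
        taf = c(`0` = "no antifungal", `1` = "with antifungal"),
        hct_band = function(x) paste0("HCT ", x, "%"))) +
    ggplot2::labs(x = "total bilirubin band (umol/L)",
                  y = "required daily dose (mg)")
}

#' Write a starting-dose table to disk
#'
#' Delimited grid with one row per stratum, plus a JSON summary
#' alongside.
#'
#' @param x A `tac_dose_table`.
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_dose_table <- function(x, path) {
  stopifnot(inherits(x, "tac_dose_table"))
  readr::write_csv(tidy(x), path, progress = FALSE)
  jsonlite::write_json(
    list(n_sim = x$n_sim, dose_grid = x$dose_grid,
         table = tidy(x)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
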