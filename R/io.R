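# Dataset input/output and validation.  The on-disk format is one
# comma-delimited row per trough observation with a header; a dialect
# object maps file column names onto the analysis names.

#' Column dialect for TDM dataset files
#'
#' Maps the column names found in a delimited file onto the names the
#' analysis uses, and records the measurement units of hematocrit and the
#' assay's lower limit of quantification.
#'
#' @param col_map Named character vector `c(analysis_name = file_name)`;
#'   only names that differ need to be given.
#' @param hct_units `"percent"` (e.g. 31.3) or `"fraction"` (0.313) in
#'   the file; values are stored as percent internally.
#' @param loq Lower limit of quantification of the trough assay (ng/mL).
#' @return A `tac_dialect` list.
#' @export
tac_dialect <- function(col_map = character(), hct_units = c("percent",
                                                             "fraction"),
                        loq = 2.0) {
  hct_units <- match.arg(hct_units)
  structure(list(col_map = col_map, hct_units = hct_units, loq = loq),
            class = "tac_dialect")
}

required_tdm_cols <- c("subject_id", "pod", "daily_dose", "c0")

#' Read a TDM dataset
#'
#' Reads a delimited text file of monitoring records (one row per trough
#' observation), applies the dialect's column mapping and unit
#' conversion, sorts rows by subject and postoperative day, and carries
#' missing covariate values forward within each subject.  Rows whose
#' dose or trough cannot be used (missing or non-positive) are not
#' silently dropped: they are returned in `attr(, "problems")` with the
#' subject id and reason.
#'
#' @param path File to read.
#' @param dialect A [tac_dialect()].
#' @return Tibble of valid observation rows, with problem rows in
#'   `attr(, "problems")`.
#' @export
read_tdm <- function(path, dialect = tac_dialect()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in names(dialect$col_map)) {
    file_col <- dialect$col_map[[nm]]
    if (!file_col %in% names(raw)) {
      abort(paste0("Mapped column not found in file: ", file_col))
    }
    names(raw)[names(raw) == file_col] <- nm
  }
  miss <- setdiff(required_tdm_cols, names(raw))
  if (length(miss)) {
    abort(paste0("Dataset file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (dialect$hct_units == "fraction" && "hct" %in% names(raw)) {
    raw$hct <- raw$hct * 100
  }
  raw <- dplyr::arrange(raw, .data$subject_id, .data$pod)
  # last observation carried forward for covariates within subject
  covariate_cols <- setdiff(names(raw), required_tdm_cols)
  raw <- raw %>%
    group_by(.data$subject_id) %>%
    mutate(across(all_of(covariate_cols),
                  ~ locf(.x))) %>%
    ungroup()
  bad_dose <- is.na(raw$daily_dose) | raw$daily_dose <= 0
  bad_c0 <- is.na(raw$c0) | raw$c0 <= 0
  bad <- bad_dose | bad_c0
  problems <- raw[bad, c("subject_id", "pod")]
  if (nrow(problems)) {
    problems$reason <- ifelse(bad_dose[bad], "invalid daily_dose",
                              "invalid c0")
  } else {
    problems$reason <- character(0)
  }
  out <- raw[!bad, ]
  attr(out, "problems") <- tibble::as_tibble(problems)
  out
}

locf <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- cumsum(!is.na(x))
  if (idx[1] == 0 && any(!is.na(x))) {
    warn("Covariate missing at a subject's first record; not filled.")
  }
  filled <- x
  notna <- which(!is.na(x))
  if (length(notna)) {
    filled <- x[notna][pmax(idx, 1)]
    filled[idx == 0] <- NA
  }
  filled
}

#' Write a TDM dataset
#'
#' @param data Observation tibble or a `tac_cohort` (its observations are
#'   written).
#' @param path File to write (comma-delimited, with header).
#' @return `path`, invisibly.
#' @export
write_tdm <- function(data, path) {
  if (inherits(data, "tac_cohort")) data <- data$observations
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a TDM dataset
#'
#' Report-only screening of observation rows: troughs below the assay's
#' quantification limit, records not at steady state, and covariates
#' outside plausibility ranges.  Nothing is removed; use
#' [exclude_flagged()] for the explicit exclusion step.
#'
#' @param data Observation tibble.
#' @param loq Lower limit of quantification (ng/mL).
#' @return Tibble with one row per flag: `subject_id`, `pod`, `rule`,
#'   `value`.
#' @export
validate_tdm <- function(data, loq = 2.0) {
  flags <- list()
  flag <- function(mask, rule, value) {
    if (any(mask, na.rm = TRUE)) {
      mask[is.na(mask)] <- FALSE
      flags[[length(flags) + 1]] <<- tibble::tibble(
        subject_id = data$subject_id[mask], pod = data$pod[mask],
        rule = rule, value = value[mask])
    }
  }
  flag(data$c0 < loq, "below_loq", data$c0)
  if ("at_steady_state" %in% names(data)) {
    flag(!data$at_steady_state, "not_steady_state",
         as.numeric(data$at_steady_state))
  }
  if ("hct" %in% names(data)) {
    flag(data$hct <= 10 | data$hct >= 65, "implausible_hct", data$hct)
  }
  if ("age" %in% names(data)) {
    flag(data$age < 18, "age_below_18", data$age)
  }
  if ("tbil" %in% names(data)) {
    flag(data$tbil <= 0, "nonpositive_tbil", data$tbil)
  }
  flag(data$daily_dose <= 0, "nonpositive_dose", data$daily_dose)
  flag(data$c0 <= 0, "nonpositive_c0", data$c0)
  if (length(flags)) dplyr::bind_rows(flags) else {
    tibble::tibble(subject_id = character(), pod = numeric(),
                   rule = character(), value = numeric())
  }
}

#' Apply exclusions from a validation report
#'
#' Removes the flagged rows for the selected rules (by default only
#' below-quantification troughs, mirroring the analysis-set rule of
#' routine assays).
#'
#' @param data Observation tibble.
#' @param report Output of [validate_tdm()].
#' @param rules Rules whose flags cause exclusion.
#' @return Filtered tibble; dropped-row count in `attr(, "n_excluded")`.
#' @export
exclude_flagged <- function(data, report, rules = "below_loq") {
  bad <- report[report$rule %in% rules, c("subject_id", "pod")]
  if (!nrow(bad)) {
    attr(data, "n_excluded") <- 0L
    return(data)
  }
  key <- paste(data$subject_id, data$pod)
  drop <- key %in% paste(bad$subject_id, bad$pod)
  out <- data[!drop, ]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Write fit results to disk
#'
#' Writes the parameter table (estimate, RSE%, 95% CI) as delimited text
#' and a machine-readable JSON summary alongside (`<path>.json`).
#'
#' @param fit A `tac_fit`.
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tac_fit"))
  readr::write_csv(tidy(fit), path, progress = FALSE)
  summary <- list(
    model = fit$spec$model,
    ofv = fit$ofv,
    n_subjects = fit$n_subj,
    n_obs = nrow(fit$data),
    converged = fit$convergence$converged,
    estimates = setNames(as.list(fit$estimates$estimate),
                         fit$estimates$parameter)
  )
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable analysis settings with their defaults: replication
#' counts for the bootstrap, visual predictive check and normalized
#' prediction distribution errors; the Monte Carlo dosing settings; the
#' assay quantification limit; and the interpretation switches.
#'
#' @param seed Integer seed.
#' @param n_bootstrap Bootstrap replicates.
#' @param n_vpc_sim VPC simulation replicates.
#' @param n_npde_sim NPDE simulation replicates.
#' @param n_mc Monte Carlo subjects per dosing scenario.
#' @param dose_grid Dose grid step (mg).
#' @param target Target trough window (ng/mL).
#' @param loq Lower limit of quantification (ng/mL).
#' @param time_factor Early-postoperative factor on the effective
#'   Michaelis constant.
#' @param hct_units Interpretation of hematocrit inside the partition
#'   model (`"fraction"` divides stored percent by 100).
#' @return A `tac_config` list.
#' @export
tac_config <- function(seed = 1L, n_bootstrap = 1000, n_vpc_sim = 1000,
                       n_npde_sim = 2000, n_mc = 200, dose_grid = 0.25,
                       target = c(8, 12), loq = 2.0, time_factor = TRUE,
                       hct_units = c("fraction", "percent")) {
  hct_units <- match.arg(hct_units)
  stopifnot(n_bootstrap >= 1, n_vpc_sim >= 1, n_npde_sim >= 1, n_mc >= 1,
            dose_grid > 0, target[1] < target[2])
  structure(list(seed = as.integer(seed), n_bootstrap = n_bootstrap,
                 n_vpc_sim = n_vpc_sim, n_npde_sim = n_npde_sim,
                 n_mc = n_mc, dose_grid = dose_grid, target = target,
                 loq = loq, time_factor = time_factor,
                 hct_units = hct_units),
            class = "tac_config")
}
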