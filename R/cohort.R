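# Synthetic TDM cohort generation: covariates and genotypes matched to the
# study population, plus trough/dose trajectories produced by the same
# dose-titration feedback loop that generates real monitoring data.

# Published summary statistics of the development cohort, used as sampling
# targets.  dist = "lognormal" for strongly right-skewed laboratory values
# (mean/median ratio > 1.3), "normal" otherwise.
cohort_covariate_table <- function() {
  tibble::tribble(
    ~name,          ~mean,   ~sd,    ~median, ~min,   ~max,   ~dist,
    "age",          50.68,   9.71,   51,      18,     74,     "normal",
    "height",       1.69,    0.06,   1.70,    1.54,   1.84,   "normal",
    "weight",       64.54,   11.85,  64,      40,     104,    "normal",
    "ffm",          50.27,   8.50,   51.49,   28.87,  68.47,  "normal",
    "graft_weight", 1310.35, 207.42, 1300,    603,    2200,   "normal",
    "hct",          31.78,   4.98,   31.3,    15.4,   53.6,   "normal",
    "alb",          37.24,   4.05,   37,      20,     51,     "normal",
    "alt",          138.99,  183.99, 69,      4,      1765,   "lognormal",
    "ast",          83.54,   143.15, 45,      9,      2547,   "lognormal",
    "tbil",         88.32,   90.11,  58.25,   5.1,    786.3,  "lognormal",
    "scr",          62.15,   28.47,  57,      19,     400,    "normal"
  )
}

# Genotype frequencies (variant-allele count 0/1/2) for recipients and
# donors at the four screened loci.
cohort_genotype_table <- function() {
  tibble::tribble(
    ~locus,      ~role,       ~p0,    ~p1,    ~p2,
    "cyp3a5",    "recipient", 0.5284, 0.4034, 0.0682,
    "cyp3a4_1g", "recipient", 0.5625, 0.3466, 0.0909,
    "sumo4",     "recipient", 0.4716, 0.4489, 0.0795,
    "nr112",     "recipient", 0.2102, 0.6591, 0.1307,
    "cyp3a5",    "donor",     0.4602, 0.4773, 0.0625,
    "cyp3a4_1g", "donor",     0.5227, 0.4261, 0.0511,
    "sumo4",     "donor",     0.4886, 0.4205, 0.0909,
    "nr112",     "donor",     0.3068, 0.4886, 0.2045
  )
}

# --- truncated-distribution moment matching ------------------------------

trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  dm <- (dnorm(a) - dnorm(b)) / z
  m <- mu + sigma * dm
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - dm^2)
  c(mean = m, sd = sqrt(v))
}

trunc_lnorm_moments <- function(mulog, sdlog, lo, hi) {
  za <- (log(lo) - mulog) / sdlog
  zb <- (log(hi) - mulog) / sdlog
  z <- pnorm(zb) - pnorm(za)
  m1 <- exp(mulog + sdlog^2 / 2) *
    (pnorm(zb - sdlog) - pnorm(za - sdlog)) / z
  m2 <- exp(2 * mulog + 2 * sdlog^2) *
    (pnorm(zb - 2 * sdlog) - pnorm(za - 2 * sdlog)) / z
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Solve for the underlying (untruncated) parameters so that the TRUNCATED
# distribution reproduces the published mean and SD.
match_trunc_params <- function(mean, sd, lo, hi, dist) {
  target <- c(mean, sd)
  obj <- function(p) {
    mo <- if (dist == "normal") {
      trunc_norm_moments(p[1], exp(p[2]), lo, hi)
    } else {
      trunc_lnorm_moments(p[1], exp(p[2]), lo, hi)
    }
    if (any(!is.finite(mo))) return(1e6)
    sum(((mo - target) / target)^2)
  }
  if (dist == "normal") {
    p0 <- c(mean, log(sd))
  } else {
    # start from the untruncated moment match
    sdl0 <- sqrt(log(1 + (sd / mean)^2))
    p0 <- c(log(mean) - sdl0^2 / 2, log(sdl0))
  }
  fit <- nlminb(p0, obj)
  list(p1 = fit$par[1], p2 = exp(fit$par[2]), objective = fit$objective)
}

rtrunc <- function(n, p1, p2, lo, hi, dist) {
  out <- numeric(0)
  draw <- if (dist == "normal") {
    function(m) rnorm(m, p1, p2)
  } else {
    function(m) rlnorm(m, p1, p2)
  }
  while (length(out) < n) {
    x <- draw(2 * (n - length(out)) + 10)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Creatinine clearance by the Cockcroft-Gault formula
#'
#' `CLCR = (140 - age) * weight / (0.818 * SCR)`, multiplied by 0.85 for
#' women; age in years, weight in kg, serum creatinine in umol/L, result
#' in mL/min.
#'
#' @param age Years.
#' @param weight kg.
#' @param scr Serum creatinine, umol/L.
#' @param female Logical or 0/1.
#' @return Creatinine clearance, mL/min.
#' @export
cockcroft_gault <- function(age, weight, scr, female) {
  (140 - age) * weight / (0.818 * scr) * ifelse(as.logical(female), 0.85, 1)
}

#' Sample baseline subject covariates
#'
#' Draws demographic and baseline laboratory covariates from truncated
#' normal (symmetric covariates) or truncated log-normal (right-skewed:
#' ALT, AST, TBIL) distributions whose truncated moments match the
#' published cohort summaries.  Creatinine clearance is computed from the
#' sampled age, weight and creatinine by [cockcroft_gault()], never
#' sampled independently.
#'
#' @param n Number of subjects.
#' @param seed Optional RNG seed.
#' @return Tibble of one row per subject (baseline values of the
#'   time-varying labs are in `hct`, `ast`, `alt`, `tbil`).
#' @export
sample_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- cohort_covariate_table()
  out <- tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)))
  out$sex <- ifelse(runif(n) < 26 / 176, "female", "male")
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    mp <- match_trunc_params(row$mean, row$sd, row$min, row$max, row$dist)
    out[[row$name]] <- rtrunc(n, mp$p1, mp$p2, row$min, row$max, row$dist)
  }
  out$clcr <- cockcroft_gault(out$age, out$weight, out$scr,
                              out$sex == "female")
  # concomitant therapy flags (subject level)
  out$taf <- as.integer(runif(n) < 56 / 176)
  out$wuzhi <- as.integer(runif(n) < 112 / 906)
  out$ccb <- as.integer(runif(n) < 65 / 906)
  out$ppi <- as.integer(runif(n) < 645 / 906)
  out$mmf <- as.integer(runif(n) < 53 / 906)
  out
}

#' Sample recipient and donor genotypes
#'
#' Draws variant-allele counts (0/1/2) at the four screened loci from the
#' published genotype frequencies, independently for recipients and
#' donors, and attaches a Hardy-Weinberg report per locus.
#'
#' @param n Number of subjects.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `<locus>_rec` / `<locus>_don` plus a
#'   derived `cyp3a5_carrier` flag (1 if the recipient carries at least
#'   one CYP3A5*1 allele); the HWE report is in `attr(, "hwe")`.
#' @export
sample_genotypes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- cohort_genotype_table()
  out <- tibble::tibble(.rows = n)
  hwe <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    col <- paste0(row$locus, "_", substr(row$role, 1, 3))
    g <- sample(0:2, n, replace = TRUE, prob = c(row$p0, row$p1, row$p2))
    out[[col]] <- g
    counts <- tabulate(g + 1L, 3L)
    hw <- hwe_test(counts)
    hwe[[length(hwe) + 1]] <- tibble::tibble(
      locus = row$locus, role = row$role,
      n0 = counts[1], n1 = counts[2], n2 = counts[3],
      chisq = hw$statistic, p_value = hw$p_value)
  }
  out$cyp3a5_carrier <- as.integer(out$cyp3a5_rec > 0)
  attr(out, "hwe") <- dplyr::bind_rows(hwe)
  out
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-squared test (1 df; the allele frequency is estimated from
#' the data) of genotype counts against Hardy-Weinberg proportions.
#'
#' @param counts Genotype counts as `c(n0, n1, n2)` for 0, 1 and 2 copies
#'   of the variant allele.
#' @return List with `statistic` and `p_value`.
#' @examples
#' hwe_test(c(93, 71, 12))
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- expected > 0
  stat <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# recovery targets and rates for time-varying labs
lab_recovery <- function() {
  list(hct = list(target = 38, rate = 0.015, cv = 0.06, lo = 15.4, hi = 53.6),
       ast = list(target = 30, rate = 0.05, cv = 0.15, lo = 9, hi = 2547),
       alt = list(target = 40, rate = 0.05, cv = 0.15, lo = 4, hi = 1765),
       tbil = list(target = 15, rate = 0.03, cv = 0.12, lo = 5.1,
                   hi = 786.3))
}

lab_course <- function(base, pod, pod0, pars) {
  val <- pars$target + (base - pars$target) * exp(-pars$rate * (pod - pod0))
  val <- val * exp(rnorm(length(pod), 0, pars$cv))
  pmin(pmax(val, pars$lo), pars$hi)
}

round_grid <- function(x, grid = 0.25) round(x / grid) * grid

eta_get <- function(eta, name) {
  if (!is.null(eta) && name %in% names(eta)) eta[[name]] else 0
}

#' Simulate one subject's monitored dose/trough course
#'
#' Emulates therapeutic drug monitoring over a sequence of visits, with
#' time-varying labs (HCT, AST, ALT, TBIL) recovering first-order toward
#' normal values with noise.
#'
#' Under a theory-based truth the course is a literal titration loop: the
#' whole-blood trough (the dependent variable) is simulated with its
#' proportional residual error at the administered dose, and the next
#' daily dose moves toward the target window by
#' `next = current * (target midpoint / observed trough)`, rounded to the
#' dose grid and limited to a +/-50% change per step.  This feedback is
#' statistically innocuous because it acts only through observed
#' dependent variables.
#'
#' Under an MM truth the dependent variable is the recorded daily dose
#' and the trough is the regressor.  Any physically generated
#' steady-state trough is proportional to `exp(eta)`, so titrating on it
#' would make the regressor deterministic in the random effect and bias
#' any subsequent conditional-likelihood refit.  The default
#' (`design = "exogenous"`) therefore draws the trough design
#' exogenously as a target-seeking monitoring trajectory (low early
#' values rising toward the target window, log-normal between- and
#' within-subject spread matched to the observed trough distribution)
#' and simulates the recorded dose conditionally with the combined
#' residual error — the standard way a dose-on-trough model is simulated
#' over a fixed design.  `design = "feedback"` retains the literal
#' titration loop (trough inverted from the administered dose at the
#' subject's random effect); use it for titration-dynamics illustrations
#' and realism checks, not for simulation-estimation experiments.
#'
#' @param subject One-row tibble of subject covariates (from
#'   [sample_covariates()] joined with [sample_genotypes()]).
#' @param truth A [tac_spec()] acting as data-generating model.
#' @param eta Named numeric vector of the subject's random effects.
#' @param target Target trough window (ng/mL).
#' @param noise Include residual error (disable for exact-identity
#'   checks).
#' @param n_visits Number of visits; default drawn as 1 + Poisson(4)
#'   (median 5).
#' @param design Trough-design mode for the MM truth (ignored for the
#'   theory truth): `"exogenous"` (default) or `"feedback"`.
#' @return Tibble of observation rows for this subject.
#' @export
simulate_tdm_course <- function(subject, truth, eta = NULL,
                                target = c(8, 12), noise = TRUE,
                                n_visits = NULL,
                                design = c("exogenous", "feedback")) {
  design <- match.arg(design)
  eta_par <- spec_eta_params(truth)
  if (is.null(eta)) eta <- setNames(rep(0, length(eta_par)), eta_par)
  if (is.null(n_visits)) n_visits <- 1 + rpois(1, 4)
  n_visits <- max(1, n_visits)
  pod1 <- sample(2:4, 1)
  pods <- pmin(pod1 + cumsum(c(0, sample(2:7, n_visits - 1,
                                         replace = TRUE))), 72)
  rec <- lab_recovery()
  rows <- tibble::tibble(
    subject_id = subject$subject_id,
    pod = pods,
    hct = lab_course(subject$hct, pods, pod1, rec$hct),
    ast = lab_course(subject$ast, pods, pod1, rec$ast),
    alt = lab_course(subject$alt, pods, pod1, rec$alt),
    tbil = lab_course(subject$tbil, pods, pod1, rec$tbil),
    alb = subject$alb, scr = subject$scr, clcr = subject$clcr,
    steroid_dose = pmax(80 - 2.5 * pods, 4) *
      exp(rnorm(n_visits, 0, 0.2)),
    taf = subject$taf, wuzhi = subject$wuzhi, ccb = subject$ccb,
    ppi = subject$ppi, mmf = subject$mmf,
    cyp3a5_carrier = subject$cyp3a5_carrier,
    at_steady_state = TRUE
  )
  for (cc in c("sex", "age", "weight", "height", "ffm", "graft_weight",
               "cyp3a5_rec", "cyp3a5_don", "cyp3a4_1g_rec",
               "cyp3a4_1g_don", "sumo4_rec", "sumo4_don", "nr112_rec",
               "nr112_don")) {
    if (cc %in% names(subject)) rows[[cc]] <- subject[[cc]]
  }

  grid <- 0.25
  mid <- mean(target)
  if (truth$model == "mm") {
    vm <- truth$fixed[["vm"]]
    cap <- floor((0.95 * vm) / grid) * grid
  } else {
    cap <- 8
  }
  dd <- sample(c(1, 1.5, 2), 1)
  dose_admin <- c0 <- dose_rec <- numeric(n_visits)
  # Exogenous trough design for the MM truth.  Clinically dosed patients
  # show troughs that scale with the (known) typical effective Michaelis
  # constant — doses live in a narrow clinical range — so the design
  # trough is that typical value times a log-normal monitoring spread
  # (subject- and visit-level).  This keeps the design independent of
  # the random effect while matching the cohort's trough distribution
  # (median ~6 ng/mL at typical covariates).
  if (truth$model == "mm" && design == "exogenous") {
    delta_i <- rnorm(1, 0, 0.25)
    u <- exp(log(0.85) + delta_i + rnorm(n_visits, 0, 0.5))
  }
  for (t in seq_len(n_visits)) {
    dd <- min(max(dd, grid), cap)
    row_t <- rows[t, ]
    if (truth$model == "mm") {
      km_i <- typical_param_rows(truth, "km", row_t) *
        exp(eta_get(eta, "km"))
      vm_i <- typical_param_rows(truth, "vm", row_t) *
        exp(eta_get(eta, "vm"))
      if (design == "exogenous") {
        km_typ_eff <- typical_param_rows(truth, "km", row_t) *
          mm_time_factor(row_t$pod, truth$time_factor)
        c0_t <- min(max(km_typ_eff * u[t], 0.3), 30)
        f <- mm_dose_pred(vm_i, km_i, c0_t, pod = row_t$pod,
                          time_factor = truth$time_factor)
        y <- f
        if (noise) {
          # a recorded dose cannot be negative: the rare sub-zero draws
          # (<1% of rows) are floored rather than redrawn, which leaves
          # the residual distribution intact elsewhere
          y <- max(f * (1 + rnorm(1, 0, truth$sigma_prop)) +
                     rnorm(1, 0, truth$sigma_add), 0.05)
        }
        dd <- y
      } else {
        c0_t <- mm_c0_solve(vm_i, km_i, dd, pod = row_t$pod,
                            time_factor = truth$time_factor)
        y <- dd
        if (noise) {
          repeat {
            y <- dd * (1 + rnorm(1, 0, truth$sigma_prop)) +
              rnorm(1, 0, truth$sigma_add)
            if (y > 0.05) break
          }
        }
      }
    } else {
      row_t$daily_dose <- dd
      ee <- c(eta_get(eta, "cl"), eta_get(eta, "v"))
      f <- theory_pred_cwb(truth, row_t, eta = ee)
      c0_t <- f
      if (noise) {
        # a measured concentration is positive; with the proportional
        # error this redraws ~0.06% of rows
        repeat {
          c0_t <- f * (1 + rnorm(1, 0, truth$sigma_prop)) +
            rnorm(1, 0, truth$sigma_add)
          if (c0_t > 0) break
        }
      }
      y <- dd
    }
    dose_admin[t] <- dd
    c0[t] <- c0_t
    dose_rec[t] <- y
    # titrate toward the target window (feedback designs only)
    if (!(truth$model == "mm" && design == "exogenous") &&
        (c0_t < target[1] || c0_t > target[2])) {
      ratio <- min(max(mid / c0_t, 0.5), 1.5)
      dd <- min(max(round_grid(dd * ratio, grid), grid), cap)
    }
  }
  rows$daily_dose <- dose_rec
  rows$dose_admin <- dose_admin
  rows$c0 <- c0
  rows
}

#' Generate a full synthetic TDM cohort
#'
#' Composition of [sample_covariates()], [sample_genotypes()] and
#' [simulate_tdm_course()]: a reproducible cohort of monitored subjects
#' with the statistical structure of the study population, together with
#' the ground truth (the generating specification and every subject's
#' random-effect draws) needed for parameter-recovery experiments.
#'
#' @param n_subjects Number of subjects.
#' @param truth Data-generating [tac_spec()].
#' @param seed RNG seed (the whole cohort is reproducible from it).
#' @param target Trough target window used by the titration policy.
#' @param noise Include residual error.
#' @param n_visits Fixed visits per subject, or `NULL` for the default
#'   1 + Poisson(4).
#' @param design Trough-design mode for MM truths; see
#'   [simulate_tdm_course()].
#' @return A `tac_cohort`: list with `observations` (analysis tibble,
#'   one row per trough record), `subjects`, `eta` (true random
#'   effects), `hwe` (genotype Hardy-Weinberg report) and `truth`.
#' @examples
#' coh <- simulate_cohort(10, tac_preset("mm_base"), seed = 1)
#' dplyr::glimpse(coh$observations)
#' @export
simulate_cohort <- function(n_subjects = 176,
                            truth = tac_preset("mm_final"),
                            seed = NULL, target = c(8, 12), noise = TRUE,
                            n_visits = NULL,
                            design = c("exogenous", "feedback")) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  subjects <- sample_covariates(n_subjects)
  genos <- sample_genotypes(n_subjects)
  subjects <- dplyr::bind_cols(subjects, genos)
  eta_par <- spec_eta_params(truth)
  eta_mat <- matrix(0, n_subjects, length(eta_par),
                    dimnames = list(NULL, eta_par))
  for (p in eta_par) {
    eta_mat[, p] <- rnorm(n_subjects, 0, sqrt(truth$omega2[[p]]))
  }
  obs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    obs[[i]] <- simulate_tdm_course(
      subjects[i, ], truth,
      eta = if (length(eta_par)) eta_mat[i, ] else NULL,
      target = target, noise = noise, n_visits = n_visits,
      design = design)
  }
  eta_tb <- tibble::tibble(subject_id = subjects$subject_id)
  for (p in eta_par) eta_tb[[paste0("eta_", p)]] <- eta_mat[, p]
  structure(
    list(observations = dplyr::bind_rows(obs), subjects = subjects,
         eta = eta_tb, hwe = attr(genos, "hwe"), truth = truth,
         seed = seed),
    class = "tac_cohort"
  )
}

#' @export
print.tac_cohort <- function(x, ...) {
  cat("<tac_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$observations), " trough observations (truth: ",
      x$truth$model, " model)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.tac_cohort <- function(x, ...) x$observations
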