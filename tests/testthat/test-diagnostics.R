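test_that("prediction-error metrics match hand computation", {
  m <- pred_error_metrics(c(10, 10, 10), c(12, 7, 10))
  expect_equal(m$mdpe, 0)
  expect_equal(m$mape, 20)
  expect_equal(m$f20, 200 / 3, tolerance = 1e-10) # boundary included
  expect_equal(m$f30, 100)
  # perfect predictions
  p <- pred_error_metrics(c(3, 5), c(3, 5), c(3, 5))
  expect_equal(unlist(p), c(mdpe = 0, mape = 0, f20 = 100, f30 = 100,
                            mdipe = 0, maipe = 0, if20 = 100,
                            if30 = 100))
  # a single observation: MDPE equals its PE
  expect_equal(pred_error_metrics(8, 10)$mdpe, 25)
  expect_error(pred_error_metrics(numeric(), numeric()), "Empty")
  # F20 <= F30 and order invariance
  set.seed(5)
  obs <- runif(50, 2, 12)
  pred <- obs * exp(rnorm(50, 0, 0.3))
  m1 <- pred_error_metrics(obs, pred)
  expect_lte(m1$f20, m1$f30)
  perm <- sample(50)
  expect_equal(pred_error_metrics(obs[perm], pred[perm]), m1)
})

test_that("fit-level prediction errors use PRED and IPRED", {
  d <- tiny_mm_data(n_subj = 20, seed = 13)
  fit <- tac_fit(d, tiny_mm_spec(), estimate_se = FALSE)
  pe <- tac_pred_errors(fit)
  expect_true(all(c("mdpe", "mape", "f20", "f30", "mdipe", "maipe",
                    "if20", "if30") %in% names(pe)))
  expect_gte(pe$if20, pe$f20 - 1e-9) # individual fit at least as close
})

test_that("bootstrap is reproducible and preserves the subject count", {
  d <- tiny_mm_data(n_subj = 12, n_obs = 4, seed = 14)
  fit <- tac_fit(d, tiny_mm_spec(), estimate_se = FALSE)
  b1 <- tac_bootstrap(fit, n = 3, seed = 99)
  b2 <- tac_bootstrap(fit, n = 3, seed = 99)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$convergence_rate, 1)
  s <- tidy(b1)
  expect_true(all(c("boot_median", "conf_low", "conf_high",
                    "bias_pct") %in% names(s)))
  expect_true(all(s$conf_low <= s$boot_median &
                    s$boot_median <= s$conf_high))
})

test_that("bootstrap intervals collapse for identical subjects", {
  base <- tibble::tibble(pod = c(5, 10, 15), c0 = c(4, 7, 10))
  base$daily_dose <- 6.1 * base$c0 / (6.19 + base$c0)
  d <- purrr::map(1:10, function(i) {
    out <- base
    out$subject_id <- sprintf("S%02d", i)
    out
  }) |> dplyr::bind_rows()
  d$daily_dose <- d$daily_dose + rep(c(0.05, -0.05), length.out = nrow(d))
  spec <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                   omega2 = c(km = 0.01), sigma_prop = 0,
                   sigma_add = 0.1)
  fit <- tac_fit(d, spec, estimate_se = FALSE)
  b <- tac_bootstrap(fit, n = 8, seed = 1)
  s <- tidy(b)
  width <- (s$conf_high - s$conf_low) / s$boot_median
  expect_true(all(width[s$parameter %in% c("vm", "km")] < 0.02))
})

test_that("VPC corrections are identity under a constant typical prediction", {
  # constant covariates and a constant trough give a constant PRED in
  # every bin, so prediction correction must not move the observations
  d <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:30), each = 3),
    pod = rep(c(5, 10, 15), 30),
    c0 = 7)
  spec <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                   omega2 = c(km = 0.3^2), sigma_prop = 0.15,
                   sigma_add = 0.2)
  set.seed(31)
  eta <- rnorm(30, 0, 0.3)
  f <- 6.1 * 7 / (6.19 * exp(eta[rep(1:30, each = 3)]) + 7)
  d$daily_dose <- f * (1 + rnorm(90, 0, 0.15)) + rnorm(90, 0, 0.2)
  v <- tac_vpc(spec, data = d, n_sim = 100, n_bins = 3, seed = 32)
  obs_med <- tapply(d$daily_dose, rep(c(5, 10, 15), 30), quantile, 0.5)
  med_rows <- v$bins[v$bins$percentile == 50, ]
  expect_equal(sort(med_rows$observed), sort(as.numeric(obs_med)),
               tolerance = 0.15)
})

test_that("VPC flags a gross location shift", {
  coh <- small_mm_cohort(60, seed = 33, n_visits = 5)
  d <- coh$observations
  d$daily_dose <- d$daily_dose * 1.5
  v <- tac_vpc(tac_preset("mm_base"), data = d, n_sim = 200, seed = 34)
  med <- v$bins[v$bins$percentile == 50, ]
  outside <- med$observed < med$conf_low | med$observed > med$conf_high
  expect_gt(mean(outside), 0.5)
})

test_that("bins honour minimum occupancy", {
  pod <- c(rep(1:7, each = 6), 50, 60, 70) # sparse right tail
  bin <- tacropop:::pod_bins(pod, n_bins = 8, min_n = 5)
  expect_true(all(table(bin) >= 5))
  expect_true(max(bin) >= 2)
})

test_that("NPDE reduces to studentization for one observation per subject", {
  set.seed(41)
  d <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:150), pod = 10, c0 = 7)
  spec <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                   omega2 = c(km = 0.4^2), sigma_prop = 0.15,
                   sigma_add = 0.2)
  eta <- rnorm(150, 0, 0.4)
  f <- 6.1 * 7 / (6.19 * exp(eta) + 7)
  d$daily_dose <- f * (1 + rnorm(150, 0, 0.15)) + rnorm(150, 0, 0.2)
  np <- tac_npde(spec, data = d, n_sim = 1000, seed = 42)
  expect_equal(length(np$npde), 150)
  expect_true(all(is.finite(np$npde)))
  # self-simulated data: roughly standard normal errors
  expect_lt(abs(mean(np$npde)), 0.2)
  expect_lt(abs(sd(np$npde) - 1), 0.2)
  expect_true(all(np$tests$p_value >= 0 & np$tests$p_value <= 1))
})

test_that("NPDE variance test rejects a model with doubled residual SD", {
  set.seed(43)
  coh <- small_mm_cohort(60, seed = 43, n_visits = 5)
  wrong <- tac_preset("mm_base")
  wrong$sigma_prop <- wrong$sigma_prop * 2
  wrong$sigma_add <- wrong$sigma_add * 2
  np <- tac_npde(wrong, data = coh$observations, n_sim = 500, seed = 44)
  p_var <- np$tests$p_value[np$tests$test == "variance"]
  expect_lt(p_var, 0.01)
})
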