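# The FOCE-I engine against independent oracles.

test_that("FOCE objective equals the exact -2LL on a linear-Gaussian model", {
  set.seed(2)
  n_subj <- 12
  n_obs <- 4
  a <- 2; b <- 0.7; om2 <- 0.8; sa <- 0.5
  subj <- rep(seq_len(n_subj), each = n_obs)
  x <- runif(n_subj * n_obs, 0, 3)
  eta <- rnorm(n_subj, 0, sqrt(om2))
  y <- a + eta[subj] + b * x + rnorm(length(x), 0, sa)
  predfun <- function(eta_mat) a + eta_mat[subj, 1] + b * x
  engine <- tacropop:::foce_eval(y, subj, n_subj, predfun, sp = 0,
                                 sa = sa, omega2 = c(om2))
  exact <- 0
  for (i in seq_len(n_subj)) {
    sel <- subj == i
    V <- om2 + diag(sa^2, n_obs) # om2 * J + sa^2 I
    r <- y[sel] - (a + b * x[sel])
    exact <- exact + n_obs * log(2 * pi) +
      as.numeric(determinant(V)$modulus) + drop(t(r) %*% solve(V, r))
  }
  expect_equal(engine$ofv, exact, tolerance = 1e-6)
})

test_that("FOCE is within 0.5% of adaptive quadrature on a nonlinear fixture", {
  # additive residual error: the comparison isolates the mode-finding and
  # linearization steps (with proportional error the exact likelihood
  # additionally integrates the eta-dependence of the residual variance,
  # which conditional-variance linearization approximates by definition)
  d <- tiny_mm_data(n_subj = 5, n_obs = 5, seed = 3, sp = 0, sa = 0.45)
  spec <- tiny_mm_spec(sp = 0, sa = 0.45)
  sid <- as.integer(factor(d$subject_id, levels = unique(d$subject_id)))
  predfun_eta <- function(e) {
    6.1 * d$c0 / (6.19 * exp(e) + d$c0)
  }
  exact <- gh_m2ll_1eta(d$daily_dose, sid, predfun_eta,
                        sp = 0, sa = 0.45, om2 = 0.36)
  foce <- foce_ofv(d, spec)
  expect_lt(abs(foce - exact) / abs(exact), 0.005)
})

test_that("conditional modes match dense grid search", {
  d <- tibble::tibble(subject_id = "A", pod = c(3, 8, 15),
                      c0 = c(4, 7, 11), daily_dose = c(2, 2.6, 3.2))
  spec <- tac_preset("mm_base")
  m <- conditional_eta_modes(d, spec)
  g <- function(e) {
    f <- 6.1 * d$c0 / (6.19 * exp(e) + d$c0)
    v <- f^2 * 0.29^2 + 0.48^2
    sum(log(v) + (d$daily_dose - f)^2 / v) + e^2 / 0.748^2
  }
  grid <- seq(-3, 3, by = 1e-4)
  expect_equal(m$eta$eta_km, grid[which.min(vapply(grid, g, numeric(1)))],
               tolerance = 1e-3)
  expect_true(m$curvature[[1]][1, 1] > 0)
  # a subject with zero residuals at eta = 0 has mode 0 (additive error;
  # with interaction the variance term itself moves the mode)
  d0 <- d
  d0$daily_dose <- 6.1 * d$c0 / (6.19 + d$c0)
  spec_add <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                       omega2 = c(km = 0.748^2), sigma_prop = 0,
                       sigma_add = 0.48)
  m0 <- conditional_eta_modes(d0, spec_add)
  expect_equal(m0$eta$eta_km, 0, tolerance = 1e-6)
})

test_that("vanishing omega reduces the objective to pooled least squares", {
  d <- tiny_mm_data(seed = 4, om = 0)
  spec_free <- tiny_mm_spec(om = 1e-8)
  spec_none <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                        omega2 = c(km = 0), sigma_prop = 0.2,
                        sigma_add = 0.4)
  expect_equal(foce_ofv(d, spec_free), foce_ofv(d, spec_none),
               tolerance = 1e-4)
})

test_that("fitting simulated data recovers parameters and supports nesting", {
  d <- tiny_mm_data(n_subj = 60, n_obs = 5, seed = 6)
  spec <- tiny_mm_spec()
  fit <- tac_fit(d, spec, estimate_se = TRUE)
  expect_true(fit$convergence$converged)
  expect_lt(fit$ofv, foce_ofv(d, spec)) # improves on the truth inits
  expect_lt(abs(coef_of(fit, "vm") - 6.1) / 6.1, 0.2)
  expect_lt(abs(coef_of(fit, "km") - 6.19) / 6.19, 0.35)
  expect_true(all(is.finite(tidy(fit)$se)))
  # nesting: adding a (useless) covariate cannot raise the optimum OFV
  spec_cov <- spec
  spec_cov$covariates <- list(covariate_effect("km", "c0x", "power",
                                               theta = 0.01,
                                               reference = 1))
  d$c0x <- runif(nrow(d), 0.5, 2)
  fit_cov <- tac_fit(d, spec_cov, estimate_se = FALSE)
  expect_lte(fit_cov$ofv, fit$ofv + 1e-3)
})

test_that("perturbed starting values reach the same optimum", {
  d <- tiny_mm_data(n_subj = 40, n_obs = 5, seed = 8)
  spec <- tiny_mm_spec()
  fit1 <- tac_fit(d, spec, estimate_se = FALSE)
  start2 <- spec
  start2$fixed <- spec$fixed * c(1.5, 0.5)
  start2$sigma_prop <- 0.35
  fit2 <- tac_fit(d, spec, start = start2, estimate_se = FALSE)
  expect_equal(fit1$ofv, fit2$ofv, tolerance = 0.1)
})

test_that("parameters can be held fixed during estimation", {
  d <- tiny_mm_data(n_subj = 20, seed = 9)
  spec <- tiny_mm_spec()
  fit <- tac_fit(d, spec, fix = "vm", estimate_se = FALSE)
  expect_false("vm" %in% tidy(fit)$parameter)
  expect_equal(fit$spec$fixed[["vm"]], 6.1)
})

test_that("shrinkage statistics behave at their limits", {
  d <- tiny_mm_data(n_subj = 30, n_obs = 5, seed = 10)
  fit <- tac_fit(d, tiny_mm_spec(), estimate_se = FALSE)
  shr <- tac_shrinkage(fit)
  expect_true(all(shr$shrinkage_pct < 100))
  # rich simulated data: eta-shrinkage is modest
  expect_lt(shr$shrinkage_pct[shr$quantity == "eta_km"], 40)
  # glance carries the same quantities
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 30)
  expect_equal(gl$ofv, fit$ofv)
})

test_that("degenerate single-subject fit reduces to least squares", {
  set.seed(11)
  d <- tibble::tibble(
    subject_id = "only", pod = seq(3, 43, by = 5),
    c0 = rlnorm(9, log(7), 0.4))
  d$daily_dose <- 6.1 * d$c0 / (6.19 + d$c0) + rnorm(9, 0, 0.3)
  spec <- tac_spec("mm", fixed = c(vm = 6.1, km = 6.19),
                   omega2 = c(km = 0), sigma_prop = 0, sigma_add = 0.3)
  fit <- tac_fit(d, spec, estimate_se = FALSE)
  # compare against direct nonlinear least squares on the same data
  nls_fit <- nls(daily_dose ~ vm * c0 / (km + c0), data = d,
                 start = list(vm = 6.1, km = 6.19))
  expect_equal(coef_of(fit, "vm"), coef(nls_fit)[["vm"]],
               tolerance = 0.02)
  expect_equal(coef_of(fit, "km"), coef(nls_fit)[["km"]],
               tolerance = 0.05)
})

test_that("augmented predictions are consistent with the fit", {
  d <- tiny_mm_data(n_subj = 15, seed = 12)
  fit <- tac_fit(d, tiny_mm_spec(), estimate_se = FALSE)
  aug <- augment_fit(fit)
  expect_equal(nrow(aug), nrow(d))
  expect_equal(aug$observed, aug$daily_dose)
  # individual predictions fit at least as well as population ones
  expect_lte(sum((aug$observed - aug$ipred)^2),
             sum((aug$observed - aug$pred)^2))
})
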