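test_that("covariate factors follow their functional forms", {
  pw <- covariate_effect("km", "hct", "power", theta = 1.16,
                         reference = 31)
  expect_equal(covariate_factor(pw, 31), 1)
  pw2 <- covariate_effect("cl", "ast", "power", theta = -0.216,
                          reference = 45)
  expect_equal(covariate_factor(pw2, 90), 2^-0.216, tolerance = 1e-12)
  expect_error(covariate_factor(pw2, -1), "positive")

  sc <- covariate_effect("cl", "taf", "scale", theta = -0.575)
  expect_equal(covariate_factor(sc, c(0, 1)), c(1, 0.425))

  em <- covariate_effect("cl", "daily_dose", "emax",
                         theta = c(emax = 3.51, e50 = 2.44))
  expect_equal(covariate_factor(em, 2.44), 3.51 / 2, tolerance = 1e-12)

  ex <- covariate_effect("v", "pod", "exponential", theta = 0.887,
                         reference = 15)
  expect_equal(covariate_factor(ex, 0), 1)
  expect_equal(covariate_factor(ex, 15), exp(0.887))
})

test_that("every multiplicative factor is 1 at the reference value", {
  forms <- list(
    covariate_effect("km", "x", "power", theta = 0.7, reference = 3),
    covariate_effect("km", "x", "scale", theta = 0.9),
    covariate_effect("km", "x", "exponential", theta = 0.4,
                     reference = 2)
  )
  ref <- c(3, 0, 0) # scale/exponential are 1 at covariate 0
  for (i in seq_along(forms)) {
    expect_equal(covariate_factor(forms[[i]], ref[i]), 1,
                 tolerance = 1e-12)
  }
})

test_that("individual_param composes typical value, covariates and eta", {
  expect_equal(individual_param(5), 5)
  # the final Km at reference covariates equals its typical value
  spec <- tac_preset("mm_final")
  km_effects <- Filter(function(ce) ce$parameter == "km",
                       spec$covariates)
  covs <- list(pod = 15, hct = 31, tbil = 58.25, cyp3a5_carrier = 0,
               taf = 0)
  expect_equal(individual_param(6.46, km_effects, covs), 6.46,
               tolerance = 1e-12)
  # clearance with the dose Emax factor at 1 mg/day
  cl_effects <- list(covariate_effect("cl", "daily_dose", "emax",
                                      theta = c(emax = 3.51,
                                                e50 = 2.44)))
  expect_equal(individual_param(234, cl_effects, list(daily_dose = 1)),
               234 * 3.51 / 3.44, tolerance = 1e-10)
  expect_equal(individual_param(2, eta = log(3)), 6, tolerance = 1e-12)
})

test_that("presets carry the published estimates", {
  mmf <- tac_preset("mm_final")
  expect_equal(mmf$fixed[["vm"]], 6.62)
  expect_equal(mmf$fixed[["km"]], 6.46)
  expect_equal(sqrt(mmf$omega2[["km"]]), 0.653)
  expect_true(mmf$time_factor)
  thb <- tac_preset("theory_base")
  expect_equal(thb$fixed[["cl"]], 456)
  expect_equal(thb$fixed[["v"]], 10700)
  expect_equal(thb$fixed[["ka"]], 4.48)
})

test_that("specs survive a YAML round trip", {
  spec <- tac_preset("theory_final")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec(spec, path)
  back <- read_spec(path)
  expect_equal(back$fixed, spec$fixed)
  expect_equal(back$omega2, spec$omega2)
  expect_equal(back$sigma_prop, spec$sigma_prop)
  expect_equal(length(back$covariates), length(spec$covariates))
  for (i in seq_along(spec$covariates)) {
    expect_equal(back$covariates[[i]]$theta, spec$covariates[[i]]$theta)
    expect_equal(back$covariates[[i]]$form, spec$covariates[[i]]$form)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(tac_spec("mm", fixed = c(vm = 6)), "must contain")
  expect_error(tac_spec("mm", fixed = c(vm = 6, km = -1),
                        sigma_prop = 0.2), "positive")
  expect_error(tac_spec("mm", fixed = c(vm = 6, km = 6)),
               "residual")
  expect_error(tac_spec("mm", fixed = c(vm = 6, km = 6),
                        omega2 = c(cl = 0.1), sigma_prop = 0.2),
               "Unknown omega2")
})
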