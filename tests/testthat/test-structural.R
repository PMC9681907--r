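test_that("MM dose prediction saturates at Vm with Km at half-maximum", {
  expect_equal(mm_dose_pred(6.62, 6.46, 6.46), 6.62 / 2)
  # saturation bound for any trough
  c0 <- exp(seq(log(0.1), log(1000), length.out = 50))
  expect_true(all(mm_dose_pred(6.62, 6.46, c0) < 6.62))
  # early-POD factor doubles the effective Km on day 5
  expect_equal(
    mm_dose_pred(6.62, 6.46, 5, pod = 5, time_factor = TRUE),
    mm_dose_pred(6.62, 2 * 6.46, 5))
  # no factor from day 10 onward
  expect_equal(
    mm_dose_pred(6.62, 6.46, 5, pod = 25, time_factor = TRUE),
    mm_dose_pred(6.62, 6.46, 5))
})

test_that("mm_c0_solve is the exact inverse of mm_dose_pred", {
  expect_equal(mm_c0_solve(6.62, 6.46, 6.62 / 2), 6.46)
  expect_equal(mm_c0_solve(6.62, 6.46, 4), 9.862595, tolerance = 1e-6)
  expect_error(mm_c0_solve(6.62, 6.46, 6.63), "accumulation")
  expect_error(mm_c0_solve(6.62, 6.46, 6.62), "accumulation")
  set.seed(1)
  for (i in 1:200) {
    vm <- runif(1, 2, 10)
    km <- runif(1, 1, 15)
    dd <- runif(1, 0.05, 0.98) * vm
    pod <- runif(1, 2, 40)
    c0 <- mm_c0_solve(vm, km, dd, pod = pod, time_factor = TRUE)
    expect_equal(mm_dose_pred(vm, km, c0, pod = pod, time_factor = TRUE),
                 dd, tolerance = 1e-12)
  }
})

test_that("whole-blood/plasma partition behaves and inverts", {
  expect_equal(plasma_to_blood(5, 0), 5)
  # blood:plasma ratio limit at vanishing plasma concentration
  expect_equal(plasma_to_blood(1e-10, 0.35) / 1e-10,
               1 + 0.35 * 418 / 3.8, tolerance = 1e-6)
  expect_equal(plasma_to_blood(0.2, 0.31), 6.679, tolerance = 1e-4)
  expect_equal(blood_to_plasma(6.679, 0.31), 0.2, tolerance = 1e-4)
  expect_equal(blood_to_plasma(0, 0.4), 0)
  # monotone increasing in cp
  cp <- seq(0.01, 50, length.out = 100)
  expect_true(all(diff(plasma_to_blood(cp, 0.31)) > 0))
  # round-trip identity over the full clinical range
  set.seed(2)
  cwb <- runif(1000, 0.01, 100)
  hct <- runif(1000, 0, 0.599)
  cp2 <- blood_to_plasma(cwb, hct)
  expect_equal(plasma_to_blood(cp2, hct), cwb, tolerance = 1e-9)
  cp3 <- runif(1000, 0.001, 100)
  expect_equal(blood_to_plasma(plasma_to_blood(cp3, hct), hct), cp3,
               tolerance = 1e-9)
})

test_that("steady-state trough equals multi-dose superposition", {
  expect_equal(ss_trough_plasma(456, 10700, 4.48, 0), 0)
  single_dose <- function(t, cl, v, ka, dose) {
    ke <- cl / v
    (dose * 1000 / v) * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
  superpose <- function(cl, v, ka, dose, tau, tad, n = 60) {
    sum(single_dose(tad + tau * (0:(n - 1)), cl, v, ka, dose))
  }
  cases <- list(c(456, 10700, 4.48, 1), c(234, 11000, 4.48, 2.5),
                c(700, 3000, 4.48, 0.5), c(100, 800, 2.0, 1.5))
  for (cs in cases) {
    expect_equal(
      ss_trough_plasma(cs[1], cs[2], cs[3], cs[4], 12, 12),
      superpose(cs[1], cs[2], cs[3], cs[4], 12, 12),
      tolerance = 1e-6)
  }
  # strictly decreasing in clearance
  cl_grid <- seq(100, 900, by = 100)
  tr <- ss_trough_plasma(cl_grid, 10700, 4.48, 1)
  expect_true(all(diff(tr) < 0))
  # absorption-elimination near-coincidence is handled
  expect_true(is.finite(ss_trough_plasma(48, 12, 4, 1)))
})

test_that("residual variance covers additive, proportional, combined", {
  expect_equal(residual_variance(0, 0.2, 0.5), 0.25)
  expect_equal(residual_variance(3, 0.204, 0), (3 * 0.204)^2)
  expect_equal(residual_variance(3, 0.204, 0.568),
               (3 * 0.204)^2 + 0.568^2)
})

test_that("theory-model prediction composes its three stages", {
  spec <- tac_preset("theory_base")
  row <- tibble::tibble(daily_dose = 3, hct = 31, pod = 10)
  cp <- ss_trough_plasma(456, 10700, 4.48, 1.5, 12, 12)
  expect_equal(theory_pred_cwb(spec, row),
               plasma_to_blood(cp, 0.31), tolerance = 1e-12)
  # raising hematocrit raises whole-blood trough, plasma unchanged
  row2 <- row
  row2$hct <- 62
  expect_gt(theory_pred_cwb(spec, row2), theory_pred_cwb(spec, row))
  # TAF co-therapy (clearance multiplier 0.425) raises the trough
  final <- tac_preset("theory_final")
  rowf <- tibble::tibble(daily_dose = 3, hct = 31, pod = 10, ast = 45,
                         cyp3a5_carrier = 0, taf = 0)
  rowt <- rowf
  rowt$taf <- 1
  expect_gt(theory_pred_cwb(final, rowt), theory_pred_cwb(final, rowf))
})

test_that("population predictions use covariate-adjusted typical values", {
  spec <- tac_preset("mm_final")
  d <- tibble::tibble(subject_id = "a", pod = c(15, 15),
                      hct = c(31, 31), tbil = c(58.25, 58.25),
                      cyp3a5_carrier = c(0, 1), taf = 0,
                      c0 = c(6.46, 6.46), daily_dose = 1)
  p <- population_pred(spec, d)
  expect_equal(p[1], 6.62 / 2)         # reference covariates, c0 = Km
  expect_gt(p[2], p[1])                # carrier: lower Km, higher dose
})
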