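test_that("Cockcroft-Gault matches the hand-computed reference", {
  expect_equal(cockcroft_gault(51, 64, 57, FALSE),
               (140 - 51) * 64 / (0.818 * 57), tolerance = 1e-12)
  expect_equal(cockcroft_gault(51, 64, 57, FALSE), 122.2,
               tolerance = 1e-3)
  expect_equal(cockcroft_gault(51, 64, 57, TRUE),
               0.85 * cockcroft_gault(51, 64, 57, FALSE))
})

test_that("Hardy-Weinberg test flags gross disequilibrium only", {
  # exactly at HW proportions: statistic ~ 0
  expect_lt(hwe_test(c(25, 50, 25))$statistic, 1e-10)
  # all-homozygote table is strongly rejected
  hw <- hwe_test(c(50, 0, 50))
  expect_equal(hw$statistic, 100)
  expect_lt(hw$p_value, 0.001)
})

test_that("sampled covariates match the cohort summaries", {
  set.seed(1)
  covs <- sample_covariates(10000)
  tab <- tacropop:::cohort_covariate_table()
  for (i in seq_len(nrow(tab))) {
    x <- covs[[tab$name[i]]]
    expect_true(all(x >= tab$min[i] & x <= tab$max[i]),
                label = paste(tab$name[i], "within range"))
    expect_lt(abs(mean(x) - tab$mean[i]) / tab$mean[i], 0.05,
              label = paste(tab$name[i], "mean within 5%"))
    expect_lt(abs(sd(x) - tab$sd[i]) / tab$sd[i], 0.05,
              label = paste(tab$name[i], "sd within 5%"))
  }
  expect_true(all(covs$age >= 18))
  # creatinine clearance is computed, not sampled
  expect_equal(covs$clcr,
               cockcroft_gault(covs$age, covs$weight, covs$scr,
                               covs$sex == "female"))
})

test_that("genotype frequencies converge to the published table", {
  set.seed(2)
  g <- sample_genotypes(10000)
  tab <- tacropop:::cohort_genotype_table()
  for (i in seq_len(nrow(tab))) {
    col <- paste0(tab$locus[i], "_", substr(tab$role[i], 1, 3))
    counts <- tabulate(g[[col]] + 1L, 3L)
    p <- c(tab$p0[i], tab$p1[i], tab$p2[i])
    # published frequencies are printed to 4 decimals; renormalize
    gof <- suppressWarnings(chisq.test(counts, p = p / sum(p)))
    expect_gt(gof$p.value, 0.01)
  }
  # recipient CYP3A5 *3/*3 fraction near 52.84%
  expect_lt(abs(mean(g$cyp3a5_rec == 0) - 0.5284), 0.02)
  expect_equal(g$cyp3a5_carrier, as.integer(g$cyp3a5_rec > 0))
  hwe <- attr(g, "hwe")
  expect_equal(nrow(hwe), 8)
  expect_true(all(hwe$p_value >= 0 & hwe$p_value <= 1))
  expect_true(all(hwe$n0 + hwe$n1 + hwe$n2 == 10000))
})

test_that("generated cohorts are reproducible and pass validation", {
  c1 <- simulate_cohort(15, tac_preset("mm_final"), seed = 5)
  c2 <- simulate_cohort(15, tac_preset("mm_final"), seed = 5)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$eta, c2$eta)
  rep <- validate_tdm(c1$observations)
  hard <- rep[!rep$rule %in% c("below_loq", "not_steady_state"), ]
  expect_equal(nrow(hard), 0)
  expect_true(all(c1$observations$at_steady_state))
  expect_true(all(c1$observations$daily_dose > 0))
  expect_true(all(c1$observations$c0 > 0))
  # rows are sorted by postoperative day within subject
  by_subj <- split(c1$observations$pod, c1$observations$subject_id)
  expect_true(all(vapply(by_subj, function(p) !is.unsorted(p),
                         logical(1))))
})

test_that("noise-free MM generation satisfies the dose-trough relation", {
  coh <- simulate_cohort(10, tac_preset("mm_final"), seed = 9,
                         noise = FALSE)
  d <- coh$observations
  eta <- coh$eta$eta_km[match(d$subject_id, coh$eta$subject_id)]
  km_i <- tacropop:::typical_param_rows(tac_preset("mm_final"), "km", d) *
    exp(eta)
  pred <- mm_dose_pred(6.62, km_i, d$c0, pod = d$pod, time_factor = TRUE)
  expect_equal(d$daily_dose, pred, tolerance = 1e-12)
})

test_that("feedback titration converges into the target window", {
  # zero random effect, no residual noise: the titration map has its
  # fixed point inside the window
  set.seed(3)
  subject <- dplyr::bind_cols(sample_covariates(1), sample_genotypes(1))
  rows <- simulate_tdm_course(subject, tac_preset("mm_base"),
                              eta = c(km = 0), noise = FALSE,
                              n_visits = 6, design = "feedback")
  expect_true(all(rows$c0[5:6] >= 8 & rows$c0[5:6] <= 12))
})

test_that("generated dose and trough levels are plausible", {
  coh <- simulate_cohort(176, tac_preset("mm_final"), seed = 12)
  dd <- coh$observations$daily_dose
  expect_lt(abs(mean(dd) - 2.73), 0.5)
  expect_gt(median(coh$observations$c0), 3)
  expect_lt(median(coh$observations$c0), 12)
  # about five visits per subject
  expect_equal(median(table(coh$observations$subject_id)), 5,
               tolerance = 1)
})

test_that("theory-truth cohorts have recoverable plasma concentrations", {
  coh <- simulate_cohort(12, tac_preset("theory_final"), seed = 4)
  d <- coh$observations
  expect_true(all(d$c0 > 0))
  cp <- blood_to_plasma(d$c0, d$hct / 100)
  expect_true(all(cp > 0 & cp < d$c0))
})
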