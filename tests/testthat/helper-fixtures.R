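# Shared fixtures: small cohorts and hand-built datasets, all generated
# in code under fixed seeds.

small_mm_cohort <- function(n = 40, seed = 7, truth = tac_preset("mm_base"),
                            ...) {
  simulate_cohort(n, truth, seed = seed, ...)
}

# A tiny hand-rolled MM dataset with exogenous troughs (no titration
# machinery), for estimation unit tests.
tiny_mm_data <- function(n_subj = 5, n_obs = 3, seed = 42,
                         vm = 6.1, km = 6.19, om = 0.6,
                         sp = 0.2, sa = 0.4) {
  set.seed(seed)
  eta <- rnorm(n_subj, 0, om)
  d <- tibble::tibble(
    subject_id = rep(sprintf("T%02d", seq_len(n_subj)), each = n_obs),
    pod = rep(seq(5, 5 + 5 * (n_obs - 1), by = 5), n_subj),
    c0 = rlnorm(n_subj * n_obs, log(6), 0.5)
  )
  f <- vm * d$c0 / (km * exp(rep(eta, each = n_obs)) + d$c0)
  d$daily_dose <- pmax(f * (1 + rnorm(nrow(d), 0, sp)) +
                         rnorm(nrow(d), 0, sa), 0.05)
  attr(d, "eta") <- eta
  d
}

tiny_mm_spec <- function(om = 0.6, sp = 0.2, sa = 0.4) {
  tac_spec("mm", fixed = c(vm = 6.1, km = 6.19), omega2 = c(km = om^2),
           sigma_prop = sp, sigma_add = sa)
}

# Exact marginal -2 log-likelihood for a 1-eta model by adaptive
# Gauss-Hermite quadrature (64 nodes), independent of the FOCE path.
gh_m2ll_1eta <- function(y, subj, predfun_eta, sp, sa, om2, n_nodes = 64) {
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (i in sort(unique(subj))) {
    sel <- subj == i
    ll <- function(e) {
      f <- predfun_eta(e)[sel]
      v <- f^2 * sp^2 + sa^2
      sum(dnorm(y[sel], f, sqrt(v), log = TRUE)) +
        dnorm(e, 0, sqrt(om2), log = TRUE)
    }
    opt <- optimize(function(e) -ll(e), c(-8, 8))
    mode <- opt$minimum
    h <- 1e-3
    curv <- -(ll(mode + h) - 2 * ll(mode) + ll(mode - h)) / h^2
    s <- 1 / sqrt(max(curv, 1e-4))
    lw <- vapply(mode + sqrt(2) * s * gh$x, ll, numeric(1)) +
      gh$x^2 + log(sqrt(2) * s * gh$w)
    m <- max(lw)
    total <- total + m + log(sum(exp(lw - m)))
  }
  -2 * total
}
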