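# Model qualification: prediction-error metrics, nonparametric bootstrap,
# prediction- and variability-corrected VPC, and normalized prediction
# distribution errors with the global test.

#' Prediction-error metrics
#'
#' Relative prediction errors `PE = (pred - obs) / obs * 100` summarized
#' as the median (MDPE, accuracy), the median absolute value (MAPE,
#' precision) and the percentage of errors within +/-20% and +/-30% (F20,
#' F30; boundary values count as inside).  When individual predictions
#' are supplied the same metrics are reported for them (MDIPE, MAIPE,
#' IF20, IF30).
#'
#' @param obs Observed values (positive).
#' @param pred Population predictions.
#' @param ipred Optional individual predictions.
#' @return A one-row tibble.
#' @examples
#' pred_error_metrics(c(10, 10, 10), c(12, 7, 10))
#' @export
pred_error_metrics <- function(obs, pred, ipred = NULL) {
  if (!length(obs)) abort("Empty input.")
  if (length(obs) != length(pred)) abort("Lengths differ.")
  if (any(obs <= 0)) abort("`obs` must be positive.")
  pe <- (pred - obs) / obs * 100
  out <- tibble::tibble(
    mdpe = median(pe), mape = median(abs(pe)),
    f20 = 100 * mean(abs(pe) <= 20), f30 = 100 * mean(abs(pe) <= 30)
  )
  if (!is.null(ipred)) {
    ipe <- (ipred - obs) / obs * 100
    out$mdipe <- median(ipe)
    out$maipe <- median(abs(ipe))
    out$if20 <- 100 * mean(abs(ipe) <= 20)
    out$if30 <- 100 * mean(abs(ipe) <= 30)
  }
  out
}

#' Prediction-error summary of a fit
#'
#' Applies [pred_error_metrics()] to a fitted model's population and
#' individual predictions.
#'
#' @param fit A `tac_fit`.
#' @return One-row tibble (MDPE, MAPE, F20, F30, MDIPE, MAIPE, IF20,
#'   IF30).
#' @export
tac_pred_errors <- function(fit) {
  aug <- augment_fit(fit)
  pred_error_metrics(aug$observed, aug$pred, aug$ipred)
}

# Simulate the dependent variable matrix (n_rows x n_sim) under a spec,
# reusing the dataset's design (doses, troughs, covariates).
simulate_dv <- function(spec, data, n_sim, subj = NULL, n_subj = NULL) {
  if (is.null(subj)) {
    sid <- factor(data$subject_id, levels = unique(data$subject_id))
    subj <- as.integer(sid)
    n_subj <- length(levels(sid))
  }
  predfun <- make_predfun(spec, data, subj)
  eta_par <- spec_eta_params(spec)
  k <- length(eta_par)
  om <- sqrt(unlist(spec$omega2[eta_par], use.names = FALSE))
  n <- nrow(data)
  out <- matrix(0, n, n_sim)
  for (s in seq_len(n_sim)) {
    eta <- matrix(rnorm(n_subj * k, 0, rep(om, each = n_subj)),
                  n_subj, max(k, 1))
    f <- predfun(eta)
    y <- f * (1 + rnorm(n, 0, spec$sigma_prop)) +
      rnorm(n, 0, spec$sigma_add)
    out[, s] <- pmax(y, 1e-6)
  }
  out
}

#' Nonparametric bootstrap of a fitted model
#'
#' Resamples subjects with replacement (keeping the original subject
#' count), refits the model on each replicate starting from the original
#' estimates, and summarizes the converged replicates by the median,
#' 2.5th-97.5th percentiles and the relative bias
#' `(bootstrap median - original) / original * 100`.
#'
#' @param fit A `tac_fit`.
#' @param n Number of bootstrap replicates.
#' @param seed RNG seed (resampling is bit-reproducible given the seed).
#' @return A `tac_bootstrap` object; `tidy()` gives the summary table.
#' @export
tac_bootstrap <- function(fit, n = 1000, seed = NULL) {
  stopifnot(inherits(fit, "tac_fit"))
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  ids <- unique(data$subject_id)
  n_subj <- length(ids)
  by_subj <- split(seq_len(nrow(data)), data$subject_id)
  reps <- vector("list", n)
  ok <- logical(n)
  for (b in seq_len(n)) {
    pick <- sample(ids, n_subj, replace = TRUE)
    idx <- unlist(by_subj[pick], use.names = FALSE)
    boot <- data[idx, ]
    # resampled copies of one subject must be distinct subjects
    boot$subject_id <- rep(sprintf("B%05d", seq_len(n_subj)),
                           lengths(by_subj[pick]))
    res <- tryCatch(
      tac_fit(boot, fit$spec, estimate_se = FALSE,
              control = list(polish = FALSE)),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence$converged) {
      ok[b] <- TRUE
      reps[[b]] <- setNames(res$estimates$estimate,
                            res$estimates$parameter)
    }
  }
  est_mat <- do.call(rbind, reps[ok])
  orig <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  summary <- tibble::tibble(
    parameter = colnames(est_mat),
    original = orig[colnames(est_mat)],
    boot_median = apply(est_mat, 2, median),
    conf_low = apply(est_mat, 2, quantile, 0.025),
    conf_high = apply(est_mat, 2, quantile, 0.975)
  )
  summary$bias_pct <- 100 * (summary$boot_median - summary$original) /
    summary$original
  conv_rate <- mean(ok)
  if (conv_rate < 0.5) {
    warn(sprintf("Bootstrap convergence rate %.0f%% is below 50%%.",
                 100 * conv_rate))
  }
  structure(list(summary = summary, estimates = est_mat,
                 convergence_rate = conv_rate, n = n),
            class = "tac_bootstrap")
}

#' @export
tidy.tac_bootstrap <- function(x, ...) x$summary

#' @export
print.tac_bootstrap <- function(x, ...) {
  cat("<tac_bootstrap> ", x$n, " replicates, ",
      sprintf("%.1f%%", 100 * x$convergence_rate), " converged\n",
      sep = "")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

# equal-count bins on POD, merging bins with fewer than `min_n` rows
pod_bins <- function(pod, n_bins, min_n = 5) {
  brk <- unique(quantile(pod, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(pod, breaks = brk, include.lowest = TRUE, labels = FALSE)
  repeat {
    counts <- table(bin)
    small <- names(counts)[counts < min_n]
    if (!length(small) || length(counts) == 1) break
    s <- as.integer(small[1])
    lev <- sort(unique(bin))
    neighbor <- if (s == max(lev)) lev[which(lev == s) - 1] else {
      lev[which(lev == s) + 1]
    }
    bin[bin == s] <- neighbor
  }
  match(bin, sort(unique(bin)))
}

#' Prediction- and variability-corrected visual predictive check
#'
#' Simulates the dependent variable under the fitted model, bins
#' observations on postoperative day (equal-count bins), corrects each
#' observed and simulated value for its typical prediction
#' (`y * bin-median PRED / PRED`) and for the bin-wise spread of the
#' simulated values, and summarizes the corrected observations by their
#' 10th/50th/90th percentiles together with simulation-based 95%
#' confidence intervals for each percentile.
#'
#' @param fit A `tac_fit`, or a [tac_spec()] together with `data` for a
#'   simulation-only check.
#' @param data Observation rows (only needed when `fit` is a spec).
#' @param n_sim Number of simulated replicates.
#' @param n_bins Number of postoperative-day bins.
#' @param seed RNG seed.
#' @return A `tac_vpc` object with `$bins` (one row per bin x
#'   percentile: observed corrected percentile and its simulation CI).
#' @export
tac_vpc <- function(fit, data = NULL, n_sim = 1000, n_bins = 8,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "tac_fit")) {
    spec <- fit$spec
    data <- fit$data
  } else {
    spec <- fit
    if (is.null(data)) abort("`data` is required when `fit` is a spec.")
    data <- dplyr::arrange(data, .data$subject_id, .data$pod)
  }
  dv <- if (spec$model == "mm") "daily_dose" else "c0"
  y <- data[[dv]]
  pred <- population_pred(spec, data)
  sims <- simulate_dv(spec, data, n_sim)
  bin <- pod_bins(data$pod, n_bins)
  n_bin <- max(bin)

  pred_bin <- as.numeric(tapply(pred, bin, median)[as.character(bin)])
  # prediction correction
  pc_obs <- y * pred_bin / pred
  pc_sim <- sims * (pred_bin / pred)
  # variability correction: per-row simulated SD scaled to its bin median
  sd_row <- apply(pc_sim, 1, sd)
  sd_row <- pmax(sd_row, 1e-12)
  sd_bin <- as.numeric(tapply(sd_row, bin, median)[as.character(bin)])
  center <- pred_bin
  pvc_obs <- center + (pc_obs - center) * sd_bin / sd_row
  pvc_sim <- center + (pc_sim - center) * (sd_bin / sd_row)

  probs <- c(0.1, 0.5, 0.9)
  rows <- list()
  for (b in seq_len(n_bin)) {
    sel <- bin == b
    obs_q <- quantile(pvc_obs[sel], probs)
    sim_q <- apply(pvc_sim[sel, , drop = FALSE], 2, quantile, probs)
    ci_lo <- apply(sim_q, 1, quantile, 0.025)
    ci_hi <- apply(sim_q, 1, quantile, 0.975)
    rows[[b]] <- tibble::tibble(
      bin = b,
      pod_mid = median(data$pod[sel]),
      n_obs = sum(sel),
      percentile = 100 * probs,
      observed = as.numeric(obs_q),
      sim_median = apply(sim_q, 1, median),
      conf_low = ci_lo,
      conf_high = ci_hi
    )
  }
  structure(list(bins = dplyr::bind_rows(rows), dv = dv, n_sim = n_sim),
            class = "tac_vpc")
}

#' @export
tidy.tac_vpc <- function(x, ...) x$bins

#' @export
print.tac_vpc <- function(x, ...) {
  inside <- with(x$bins, mean(observed >= conf_low &
                                observed <= conf_high))
  cat("<tac_vpc> ", x$n_sim, " simulations; ",
      sprintf("%.0f%%", 100 * inside),
      " of bin percentiles inside their 95% CI\n", sep = "")
  invisible(x)
}

#' @export
autoplot.tac_vpc <- function(object, ...) {
  b <- object$bins
  b$percentile <- factor(b$percentile)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$pod_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high,
                                      fill = .data$percentile),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::labs(x = "postoperative day",
                  y = paste("corrected", object$dv),
                  colour = "percentile", fill = "percentile")
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates the observation vector under the model,
#' centers and decorrelates both simulations and observations with the
#' lower-triangular factor of the simulated covariance, converts the
#' rank of each decorrelated observation among its simulations (with the
#' 1/(2 n_sim) continuity correction) through the standard-normal
#' quantile function, and tests the resulting errors globally: t-test of
#' zero mean, chi-squared test of unit variance and Shapiro-Wilk
#' normality, Bonferroni-combined (`adjusted p = 3 * min p`, capped at
#' 1).
#'
#' @inheritParams tac_vpc
#' @param n_sim Number of simulated replicates (per observation).
#' @return A `tac_npde` object: `$npde` per-observation errors,
#'   `$tests` tibble with the component and global p-values.
#' @export
tac_npde <- function(fit, data = NULL, n_sim = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "tac_fit")) {
    spec <- fit$spec
    data <- fit$data
  } else {
    spec <- fit
    if (is.null(data)) abort("`data` is required when `fit` is a spec.")
    data <- dplyr::arrange(data, .data$subject_id, .data$pod)
  }
  dv <- if (spec$model == "mm") "daily_dose" else "c0"
  y <- data[[dv]]
  sid <- factor(data$subject_id, levels = unique(data$subject_id))
  subj <- as.integer(sid)
  n_subj <- length(levels(sid))
  sims <- simulate_dv(spec, data, n_sim, subj = subj, n_subj = n_subj)

  npde <- numeric(length(y))
  ridged <- 0L
  for (i in seq_len(n_subj)) {
    sel <- which(subj == i)
    s <- sims[sel, , drop = FALSE]
    mu <- rowMeans(s)
    sc <- s - mu
    v <- sc %*% t(sc) / (n_sim - 1)
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) {
      ridged <- ridged + 1L
      v <- v + diag(1e-8 * mean(diag(v)) + 1e-12, nrow(v))
      ch <- chol(v)
    }
    linv_apply <- function(m) forwardsolve(t(ch), m)
    ystar <- linv_apply(y[sel] - mu)
    sstar <- linv_apply(sc)
    pd <- (rowSums(sstar < ystar)) / n_sim
    pd <- pmin(pmax(pd, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    npde[sel] <- qnorm(pd)
  }
  n <- length(npde)
  p_mean <- t.test(npde)$p.value
  s2 <- var(npde)
  stat_v <- (n - 1) * s2
  p_var <- 2 * min(pchisq(stat_v, n - 1),
                   pchisq(stat_v, n - 1, lower.tail = FALSE))
  sw <- if (n > 5000) sample(npde, 5000) else npde
  p_norm <- shapiro.test(sw)$p.value
  p_global <- min(1, 3 * min(p_mean, p_var, p_norm))
  tests <- tibble::tibble(
    test = c("mean", "variance", "normality", "global"),
    p_value = c(p_mean, p_var, p_norm, p_global))
  structure(list(npde = npde, tests = tests, data = data, dv = dv,
                 n_sim = n_sim, n_ridged = ridged),
            class = "tac_npde")
}

#' @export
tidy.tac_npde <- function(x, ...) x$tests

#' @export
print.tac_npde <- function(x, ...) {
  cat("<tac_npde> ", length(x$npde), " observations, ", x$n_sim,
      " simulations\n", sep = "")
  print(as.data.frame(x$tests), digits = 3)
  invisible(x)
}

#' @param type `"qq"` for the normal quantile-quantile panel, `"pod"`
#'   for errors against postoperative day.
#' @rdname tac_npde
#' @export
autoplot.tac_npde <- function(object, type = c("qq", "pod"), ...) {
  type <- match.arg(type)
  d <- tibble::tibble(npde = object$npde, pod = object$data$pod)
  if (type == "qq") {
    ggplot2::ggplot(d, ggplot2::aes(sample = .data$npde)) +
      ggplot2::stat_qq(alpha = 0.4, size = 0.8) +
      ggplot2::stat_qq_line() +
      ggplot2::labs(title = "NPDE normal Q-Q")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$pod, y = .data$npde)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_hline(yintercept = c(-1.96, 0, 1.96),
                          linetype = c(2, 1, 2)) +
      ggplot2::labs(x = "postoperative day")
  }
}
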