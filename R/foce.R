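# First-order conditional estimation with interaction (FOCE-I).
#
# The engine is generic over a prediction function eta -> per-row
# predictions, so the same code serves the MM and theory-based models (and
# test fixtures).  Inner problem: per-subject penalized objective
#   g_i(eta) = sum_j [ log v_j(eta) + (y_j - f_j(eta))^2 / v_j(eta) ]
#              + eta' Omega^{-1} eta,
# with v_j evaluated at the conditional prediction (the "interaction").
# It is minimized for all subjects simultaneously by damped Gauss-Newton
# with exact gradients (model derivatives by central differences).  The
# marginal -2 log-likelihood then linearizes f about the conditional mode:
#   V_i = G Omega G' + diag(v),  res = y - f(eta_hat) + G eta_hat,
#   -2ll_i = n_i log(2pi) + log det V_i + res' V_i^{-1} res,
# assembled by the Woodbury identity (Omega is diagonal, rank <= 2).

V_BIG <- 1e12

# Vectorized inner-mode search. `predfun(eta_mat)` returns per-row
# predictions for an n_subj x k matrix of random effects.
foce_inner <- function(y, subj, n_subj, predfun, sp, sa, omega2,
                       eta0 = NULL, tol = 1e-6, max_iter = 80) {
  k <- length(omega2)
  w_inv <- 1 / omega2
  h <- 1e-4

  g_of <- function(e) {
    f <- predfun(e)
    if (any(!is.finite(f))) {
      return(list(g = rep(V_BIG, n_subj), f = f, v = NULL, ok = FALSE))
    }
    v <- pmax(f^2 * sp^2 + sa^2, 1e-12)
    contrib <- log(v) + (y - f)^2 / v
    g <- rowsum(contrib, subj, reorder = TRUE)[, 1] +
      as.vector((e^2) %*% w_inv)
    list(g = g, f = f, v = v, ok = TRUE)
  }

  # Candidate starts per subject: zero, the warm start, and a crude
  # data-driven guess on the first random effect (the conditional
  # objective can be multimodal for two-random-effect models, and the
  # per-subject best start keeps the objective well defined and
  # start-independent).
  starts <- list(matrix(0, n_subj, k))
  if (!is.null(eta0) && all(dim(eta0) == c(n_subj, k)) &&
      all(is.finite(eta0))) {
    starts <- c(starts, list(eta0))
  }
  z <- g_of(starts[[1]])
  if (z$ok) {
    ratio <- rowsum(log(pmax(y, 1e-6)) - log(pmax(z$f, 1e-6)),
                    subj, reorder = TRUE)[, 1] / tabulate(subj, n_subj)
    for (sgn in c(-1, 1)) {
      guess <- matrix(0, n_subj, k)
      guess[, 1] <- pmin(pmax(sgn * ratio, -2.5), 2.5)
      starts <- c(starts, list(guess))
    }
  }
  eta <- starts[[1]]
  cur <- z
  if (!cur$ok) return(list(eta = eta, g = cur$g, f = cur$f, v = cur$v,
                           fd = NULL, converged = FALSE))
  for (s in starts[-1]) {
    alt <- g_of(s)
    if (!alt$ok) next
    better <- alt$g < cur$g
    if (any(better)) {
      eta[better, ] <- s[better, ]
      cur <- g_of(eta)
    }
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # model derivatives wrt each eta dimension, by central differences
    fd <- matrix(0, length(y), k)
    bad <- FALSE
    for (d in seq_len(k)) {
      ep <- eta; ep[, d] <- ep[, d] + h
      em <- eta; em[, d] <- em[, d] - h
      fp <- predfun(ep); fm <- predfun(em)
      if (any(!is.finite(fp)) || any(!is.finite(fm))) { bad <- TRUE; break }
      fd[, d] <- (fp - fm) / (2 * h)
    }
    if (bad) break
    r <- y - cur$f
    v <- cur$v
    vp_base <- 2 * sp^2 * cur$f # dv/df
    grad <- matrix(0, n_subj, k)
    for (d in seq_len(k)) {
      vd <- vp_base * fd[, d]
      term <- vd / v - 2 * r * fd[, d] / v - r^2 * vd / v^2
      grad[, d] <- rowsum(term, subj, reorder = TRUE)[, 1] +
        2 * eta[, d] * w_inv[d]
    }
    gmax <- apply(abs(grad), 1, max)
    if (max(gmax) < tol) { converged <- TRUE; break }

    # Gauss-Newton curvature (positive definite)
    if (k == 1) {
      h11 <- rowsum(2 * fd[, 1]^2 / v, subj, reorder = TRUE)[, 1] +
        2 * w_inv[1]
      step <- -grad[, 1] / h11
      step <- matrix(step, ncol = 1)
    } else {
      h11 <- rowsum(2 * fd[, 1]^2 / v, subj, reorder = TRUE)[, 1] +
        2 * w_inv[1]
      h22 <- rowsum(2 * fd[, 2]^2 / v, subj, reorder = TRUE)[, 1] +
        2 * w_inv[2]
      h12 <- rowsum(2 * fd[, 1] * fd[, 2] / v, subj, reorder = TRUE)[, 1]
      det <- pmax(h11 * h22 - h12^2, 1e-12)
      s1 <- -(h22 * grad[, 1] - h12 * grad[, 2]) / det
      s2 <- -(h11 * grad[, 2] - h12 * grad[, 1]) / det
      step <- cbind(s1, s2)
    }
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -2), 2) # trust region on the log scale

    # backtracking line search, per subject
    alpha <- rep(1, n_subj)
    active <- rep(TRUE, n_subj)
    new_eta <- eta
    for (ls in 1:6) {
      trial <- eta + step * alpha
      out <- g_of(trial)
      if (!out$ok) { alpha <- alpha / 2; next }
      improved <- out$g <= cur$g + 1e-12
      new_eta[improved & active, ] <- trial[improved & active, ]
      active <- active & !improved
      if (!any(active)) break
      alpha[active] <- alpha[active] / 2
    }
    if (all(active)) break # no subject improved: at (numerical) optimum
    prev_g <- cur$g
    eta <- new_eta
    cur <- g_of(eta)
    if (max(abs(prev_g - cur$g)) < 1e-12 * (1 + max(abs(cur$g)))) {
      converged <- TRUE
      break
    }
  }

  # final derivatives at the mode
  fd <- matrix(0, length(y), k)
  for (d in seq_len(k)) {
    ep <- eta; ep[, d] <- ep[, d] + h
    em <- eta; em[, d] <- em[, d] - h
    fd[, d] <- (predfun(ep) - predfun(em)) / (2 * h)
  }
  list(eta = eta, g = cur$g, f = cur$f, v = cur$v, fd = fd,
       converged = converged)
}

# FOCE-I marginal -2LL from the inner solution, via the Woodbury identity.
foce_assemble <- function(y, subj, n_subj, inner, omega2) {
  k <- length(omega2)
  f <- inner$f
  v <- inner$v
  if (is.null(v) || any(!is.finite(f))) return(V_BIG)
  fd <- inner$fd
  eta <- inner$eta
  r <- y - f + as.vector(rowSums(fd * eta[subj, , drop = FALSE]))
  n_i <- tabulate(subj, n_subj)
  sum_logv <- rowsum(log(v), subj, reorder = TRUE)[, 1]
  rDr <- rowsum(r^2 / v, subj, reorder = TRUE)[, 1]
  if (k == 1) {
    m11 <- rowsum(fd[, 1]^2 / v, subj, reorder = TRUE)[, 1]
    u1 <- rowsum(fd[, 1] * r / v, subj, reorder = TRUE)[, 1]
    a <- 1 + omega2[1] * m11
    logdet <- sum_logv + log(a)
    quad <- rDr - omega2[1] * u1^2 / a
  } else {
    m11 <- rowsum(fd[, 1]^2 / v, subj, reorder = TRUE)[, 1]
    m22 <- rowsum(fd[, 2]^2 / v, subj, reorder = TRUE)[, 1]
    m12 <- rowsum(fd[, 1] * fd[, 2] / v, subj, reorder = TRUE)[, 1]
    u1 <- rowsum(fd[, 1] * r / v, subj, reorder = TRUE)[, 1]
    u2 <- rowsum(fd[, 2] * r / v, subj, reorder = TRUE)[, 1]
    detb <- (1 + omega2[1] * m11) * (1 + omega2[2] * m22) -
      omega2[1] * omega2[2] * m12^2
    logdet <- sum_logv + log(pmax(detb, 1e-300))
    # (Omega^{-1} + M)^{-1} applied to u, closed form 2x2
    a11 <- 1 / omega2[1] + m11
    a22 <- 1 / omega2[2] + m22
    deta <- pmax(a11 * a22 - m12^2, 1e-300)
    quad <- rDr - (a22 * u1^2 - 2 * m12 * u1 * u2 + a11 * u2^2) / deta
  }
  ll2 <- n_i * log(2 * pi) + logdet + quad
  if (any(!is.finite(ll2))) return(V_BIG)
  sum(ll2)
}

# Full generic FOCE-I evaluation; `state` is an environment carrying
# warm-start modes across evaluations.
foce_eval <- function(y, subj, n_subj, predfun, sp, sa, omega2,
                      state = NULL) {
  if (length(omega2) == 0) {
    # no random effects: extended least squares
    f <- predfun(matrix(0, n_subj, 0))
    if (any(!is.finite(f))) return(list(ofv = V_BIG))
    v <- pmax(f^2 * sp^2 + sa^2, 1e-12)
    ofv <- sum(log(v) + (y - f)^2 / v) + length(y) * log(2 * pi)
    return(list(ofv = ofv, f = f, v = v,
                eta = matrix(0, n_subj, 0), converged = TRUE))
  }
  eta0 <- if (!is.null(state) && !is.null(state$eta)) state$eta else NULL
  inner <- foce_inner(y, subj, n_subj, predfun, sp, sa, omega2, eta0)
  ofv <- foce_assemble(y, subj, n_subj, inner, omega2)
  if (!is.null(state) && is.finite(ofv) && ofv < V_BIG) {
    state$eta <- inner$eta
  }
  list(ofv = ofv, f = inner$f, v = inner$v, eta = inner$eta,
       fd = inner$fd, converged = inner$converged)
}

# --- parameter packing ---------------------------------------------------

# Transformed-scale parameter map for a spec: positive parameters on the
# log scale, covariate coefficients unconstrained, scale coefficients via
# theta = exp(x) - 1 (keeps the 1 + theta multiplier positive).
par_map <- function(spec, fix = character()) {
  rows <- list()
  add <- function(label, type, get, set) {
    rows[[length(rows) + 1]] <<- list(label = label, type = type,
                                      get = get, set = set)
  }
  for (p in setdiff(names(spec$fixed), "ka")) {
    local({
      pp <- p
      add(pp, "log",
          function(s) log(s$fixed[[pp]]),
          function(s, val) { s$fixed[[pp]] <- exp(val); s })
    })
  }
  for (i in seq_along(spec$covariates)) {
    ce <- spec$covariates[[i]]
    base <- paste0("beta_", ce$parameter, "_", ce$covariate)
    local({
      ii <- i
      if (ce$form == "emax") {
        add(paste0(base, "_emax"), "log",
            function(s) log(s$covariates[[ii]]$theta[["emax"]]),
            function(s, val) {
              s$covariates[[ii]]$theta[["emax"]] <- exp(val); s
            })
        add(paste0(base, "_e50"), "log",
            function(s) log(s$covariates[[ii]]$theta[["e50"]]),
            function(s, val) {
              s$covariates[[ii]]$theta[["e50"]] <- exp(val); s
            })
      } else if (ce$form == "scale") {
        add(base, "expm1",
            function(s) log(1 + s$covariates[[ii]]$theta),
            function(s, val) {
              s$covariates[[ii]]$theta <- exp(val) - 1; s
            })
      } else {
        add(base, "ident",
            function(s) s$covariates[[ii]]$theta,
            function(s, val) { s$covariates[[ii]]$theta <- val; s })
      }
    })
  }
  for (p in spec_eta_params(spec)) {
    local({
      pp <- p
      add(paste0("omega2_", pp), "log",
          function(s) log(s$omega2[[pp]]),
          function(s, val) { s$omega2[[pp]] <- exp(val); s })
    })
  }
  if (spec$sigma_prop > 0) {
    add("sigma_prop", "log",
        function(s) log(s$sigma_prop),
        function(s, val) { s$sigma_prop <- exp(val); s })
  }
  if (spec$sigma_add > 0) {
    add("sigma_add", "log",
        function(s) log(s$sigma_add),
        function(s, val) { s$sigma_add <- exp(val); s })
  }
  rows <- rows[!vapply(rows, function(r) r$label %in% fix, logical(1))]
  rows
}

pm_pack <- function(pmap, spec) {
  setNames(vapply(pmap, function(r) r$get(spec), numeric(1)),
           vapply(pmap, function(r) r$label, character(1)))
}

pm_unpack <- function(pmap, spec, x) {
  for (i in seq_along(pmap)) spec <- pmap[[i]]$set(spec, x[[i]])
  spec
}

# natural-scale value and derivative d(natural)/d(transformed)
pm_natural <- function(pmap, x) {
  nat <- numeric(length(pmap))
  dnat <- numeric(length(pmap))
  for (i in seq_along(pmap)) {
    nat[i] <- switch(pmap[[i]]$type,
                     log = exp(x[[i]]),
                     expm1 = exp(x[[i]]) - 1,
                     ident = x[[i]])
    dnat[i] <- switch(pmap[[i]]$type,
                      log = exp(x[[i]]),
                      expm1 = exp(x[[i]]),
                      ident = 1)
  }
  list(value = nat, deriv = dnat)
}

# --- dataset context -----------------------------------------------------

foce_context <- function(data, spec) {
  dv <- if (spec$model == "mm") "daily_dose" else "c0"
  need <- unique(c("subject_id", "pod", "daily_dose", "c0",
                   if (spec$model == "theory") "hct",
                   vapply(spec$covariates, function(ce) ce$covariate,
                          character(1))))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Dataset lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  data <- dplyr::arrange(data, .data$subject_id, .data$pod)
  sid <- factor(data$subject_id, levels = unique(data$subject_id))
  subj <- as.integer(sid)
  list(data = data, y = data[[dv]], subj = subj,
       n_subj = length(levels(sid)), subject_ids = levels(sid))
}

#' FOCE-I objective function value
#'
#' Approximate -2 log marginal likelihood of a dataset under a model
#' specification, by first-order conditional estimation with interaction.
#'
#' @param data Observation rows (one row per trough record).
#' @param spec A [tac_spec()].
#' @return The objective function value (scalar).
#' @export
foce_ofv <- function(data, spec) {
  ctx <- foce_context(data, spec)
  predfun <- make_predfun(spec, ctx$data, ctx$subj)
  omega2 <- spec$omega2[spec_eta_params(spec)]
  foce_eval(ctx$y, ctx$subj, ctx$n_subj, predfun,
            spec$sigma_prop, spec$sigma_add, omega2)$ofv
}

#' Conditional random-effect modes
#'
#' Per-subject empirical Bayes modes of the random effects under a fixed
#' model specification, with the Gauss-Newton curvature of the penalized
#' objective at the mode.
#'
#' @inheritParams foce_ofv
#' @return A list with `eta` (tibble: `subject_id` then one `eta_<param>`
#'   column per random effect) and `curvature` (list of per-subject
#'   matrices).
#' @export
conditional_eta_modes <- function(data, spec) {
  ctx <- foce_context(data, spec)
  predfun <- make_predfun(spec, ctx$data, ctx$subj)
  eta_par <- spec_eta_params(spec)
  omega2 <- spec$omega2[eta_par]
  inner <- foce_inner(ctx$y, ctx$subj, ctx$n_subj, predfun,
                      spec$sigma_prop, spec$sigma_add, omega2)
  k <- length(omega2)
  curv <- vector("list", ctx$n_subj)
  for (d1 in seq_len(k)) {
    for (d2 in seq_len(d1)) {
      hv <- rowsum(2 * inner$fd[, d1] * inner$fd[, d2] / inner$v,
                   ctx$subj, reorder = TRUE)[, 1]
      if (d1 == d2) hv <- hv + 2 / omega2[d1]
      for (i in seq_len(ctx$n_subj)) {
        if (is.null(curv[[i]])) curv[[i]] <- matrix(0, k, k)
        curv[[i]][d1, d2] <- curv[[i]][d2, d1] <- hv[i]
      }
    }
  }
  eta_tb <- tibble::tibble(subject_id = ctx$subject_ids)
  for (d in seq_len(k)) eta_tb[[paste0("eta_", eta_par[d])]] <- inner$eta[, d]
  list(eta = eta_tb, curvature = curv, converged = inner$converged)
}

# --- maximum-likelihood fit ----------------------------------------------

#' Fit a population pharmacokinetic model by FOCE-I
#'
#' Maximizes the FOCE-I approximate marginal likelihood over the model's
#' fixed effects, covariate coefficients, between-subject variances and
#' residual components.  Positive parameters are optimized on the log
#' scale; scale-form covariate coefficients via `log(1 + theta)`.
#' Standard errors come from the numerical Hessian of the objective at
#' the optimum (`Var = 2 H^{-1}`, since the objective is -2 log L).
#'
#' @param data Observation rows (see [simulate_cohort()] for the layout).
#' @param spec A [tac_spec()] giving the model structure; its parameter
#'   values are the starting values unless `start` overrides them.
#' @param start Optional `tac_spec` supplying starting values.
#' @param fix Character vector of parameter labels to hold at their
#'   starting values (see `tidy()` output for labels).
#' @param estimate_se Compute the covariance step (numerical Hessian).
#' @param control List: `iter_max`, `eval_max`, `rel_tol` for the outer
#'   optimizer; `polish` (default `TRUE`) adds a Nelder-Mead stage that
#'   guards against stalls on flat likelihood ridges.
#' @return A `tac_fit` object; see [tidy.tac_fit()], [glance.tac_fit()],
#'   [autoplot.tac_fit()].
#' @export
tac_fit <- function(data, spec, start = NULL, fix = character(),
                    estimate_se = TRUE, control = list()) {
  ctrl <- modifyList(list(iter_max = 400, eval_max = 2000,
                          rel_tol = 1e-9, polish = TRUE), control)
  if (!is.null(start)) {
    spec0 <- start
  } else {
    spec0 <- spec
  }
  ctx <- foce_context(data, spec0)
  pmap <- par_map(spec0, fix = fix)
  if (!length(pmap)) abort("No free parameters to estimate.")
  eta_par <- spec_eta_params(spec0)
  state <- new.env(parent = emptyenv())
  n_eval <- 0L

  objective <- function(x) {
    n_eval <<- n_eval + 1L
    s <- pm_unpack(pmap, spec0, x)
    predfun <- tryCatch(make_predfun(s, ctx$data, ctx$subj),
                        error = function(e) NULL)
    if (is.null(predfun)) return(V_BIG)
    foce_eval(ctx$y, ctx$subj, ctx$n_subj, predfun,
              s$sigma_prop, s$sigma_add, s$omega2[eta_par],
              state = state)$ofv
  }

  x0 <- pm_pack(pmap, spec0)
  ofv0 <- objective(x0)
  if (ofv0 >= V_BIG) abort("Starting values give a non-finite objective.")
  opt <- nlminb(x0, objective,
                control = list(iter.max = ctrl$iter_max,
                               eval.max = ctrl$eval_max,
                               rel.tol = ctrl$rel_tol))
  # verification restart from the optimum: with warm-started inner modes
  # the first pass can stop on a "false convergence" signal while already
  # at the optimum; accept if the restart cannot improve materially
  opt2 <- nlminb(opt$par, objective,
                 control = list(iter.max = ctrl$iter_max,
                                eval.max = ctrl$eval_max,
                                rel.tol = ctrl$rel_tol))
  if (opt2$objective <= opt$objective) opt <- opt2
  converged <- (opt$convergence == 0 ||
                  abs(opt2$objective - opt$objective) < 0.05) &&
    opt$objective <= ofv0 + 1e-6
  # derivative-free polish: gradient-based search can stall on the flat
  # likelihood ridges of weakly identified parameter pairs (apparent
  # volume and its variability in particular)
  if (isTRUE(ctrl$polish)) {
    np <- optim(opt$par, objective, method = "Nelder-Mead",
                control = list(maxit = min(50 * length(opt$par), 750),
                               reltol = 1e-10))
    if (np$value < opt$objective - 1e-8) {
      opt3 <- nlminb(np$par, objective,
                     control = list(iter.max = ctrl$iter_max,
                                    eval.max = ctrl$eval_max,
                                    rel.tol = ctrl$rel_tol))
      if (opt3$objective <= np$value) {
        opt <- opt3
      } else {
        opt <- list(par = np$par, objective = np$value,
                    convergence = 0, message = "Nelder-Mead polish",
                    iterations = np$counts[[1]])
      }
      converged <- converged && opt$objective <= ofv0 + 1e-6
    }
  }
  x_hat <- opt$par
  spec_hat <- pm_unpack(pmap, spec0, x_hat)

  # final inner solve at the optimum
  predfun <- make_predfun(spec_hat, ctx$data, ctx$subj)
  fin <- foce_eval(ctx$y, ctx$subj, ctx$n_subj, predfun,
                   spec_hat$sigma_prop, spec_hat$sigma_add,
                   spec_hat$omega2[eta_par], state = state)

  # covariance step
  nat <- pm_natural(pmap, x_hat)
  se_nat <- rep(NA_real_, length(pmap))
  vcov_t <- NULL
  se_ok <- FALSE
  if (estimate_se) {
    hess <- tryCatch(optimHess(x_hat, objective), error = function(e) NULL)
    if (!is.null(hess)) {
      vcov_t <- tryCatch(2 * solve(hess), error = function(e) NULL)
      if (!is.null(vcov_t) && all(diag(vcov_t) > 0)) {
        se_nat <- sqrt(diag(vcov_t)) * abs(nat$deriv)
        se_ok <- TRUE
      }
    }
  }

  labels <- vapply(pmap, function(r) r$label, character(1))
  type <- dplyr::case_when(
    grepl("^beta_", labels) ~ "covariate",
    grepl("^omega2_", labels) ~ "omega2",
    grepl("^sigma_", labels) ~ "sigma",
    TRUE ~ "fixed"
  )
  estimates <- tibble::tibble(
    parameter = labels,
    type = type,
    estimate = nat$value,
    se = se_nat,
    rse_pct = 100 * se_nat / abs(nat$value),
    conf_low = nat$value - 1.96 * se_nat,
    conf_high = nat$value + 1.96 * se_nat
  )

  eta_tb <- tibble::tibble(subject_id = ctx$subject_ids)
  if (length(eta_par)) {
    for (d in seq_along(eta_par)) {
      eta_tb[[paste0("eta_", eta_par[d])]] <- fin$eta[, d]
    }
  }

  structure(
    list(spec = spec_hat, start = spec0, data = ctx$data,
         estimates = estimates, ofv = fin$ofv, eta = eta_tb,
         pred_ind = fin$f, var_ind = fin$v,
         vcov_trans = vcov_t, par_labels = labels,
         convergence = list(converged = converged, se_ok = se_ok,
                            outer_message = opt$message,
                            iterations = opt$iterations,
                            evaluations = n_eval,
                            ofv_start = ofv0),
         subj = ctx$subj, n_subj = ctx$n_subj),
    class = "tac_fit"
  )
}

#' Shrinkage of random effects and weighted residuals
#'
#' eta-shrinkage is `100 * (1 - SD(eta modes) / omega)` per random effect;
#' eps-shrinkage is `100 * (1 - SD(IWRES))` with
#' `IWRES = (y - f_ind) / sqrt(Var_ind)`.
#'
#' @param fit A [tac_fit()] result.
#' @return A tibble with columns `quantity` and `shrinkage_pct`.
#' @export
tac_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  eta_par <- spec_eta_params(fit$spec)
  rows <- list()
  for (p in eta_par) {
    om <- sqrt(fit$spec$omega2[[p]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = paste0("eta_", p),
      shrinkage_pct = 100 * (1 - sd(fit$eta[[paste0("eta_", p)]]) / om)
    )
  }
  y <- fit$data[[if (fit$spec$model == "mm") "daily_dose" else "c0"]]
  iwres <- (y - fit$pred_ind) / sqrt(fit$var_ind)
  rows[[length(rows) + 1]] <- tibble::tibble(
    quantity = "eps", shrinkage_pct = 100 * (1 - sd(iwres)))
  dplyr::bind_rows(rows)
}

#' @export
print.tac_fit <- function(x, ...) {
  cat("<tac_fit> ", x$spec$model, " model, ", x$n_subj, " subjects, ",
      nrow(x$data), " observations\n", sep = "")
  cat("  OFV: ", format(x$ofv, digits = 8),
      if (!x$convergence$converged) "  [NOT CONVERGED]" else "",
      "\n", sep = "")
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Tidy parameter estimates of a fit
#'
#' @param x A `tac_fit`.
#' @param ... Unused.
#' @return A tibble: `parameter`, `type`, `estimate`, `se`, `rse_pct`,
#'   `conf_low`, `conf_high`.
#' @export
tidy.tac_fit <- function(x, ...) x$estimates

#' One-row fit summary
#'
#' @param x A `tac_fit`.
#' @param ... Unused.
#' @return Tibble with the objective function value, counts, convergence
#'   flag and shrinkage summaries.
#' @export
glance.tac_fit <- function(x, ...) {
  shr <- tac_shrinkage(x)
  tibble::tibble(
    ofv = x$ofv,
    n_subjects = x$n_subj,
    n_obs = nrow(x$data),
    n_parameters = nrow(x$estimates),
    converged = x$convergence$converged,
    eps_shrinkage_pct = shr$shrinkage_pct[shr$quantity == "eps"],
    max_eta_shrinkage_pct = if (any(shr$quantity != "eps")) {
      max(shr$shrinkage_pct[shr$quantity != "eps"])
    } else {
      NA_real_
    }
  )
}

#' Estimated value of one parameter
#'
#' Convenience accessor for a fitted parameter by its label.
#'
#' @param fit A `tac_fit`.
#' @param label Parameter label as shown by `tidy()`.
#' @return The natural-scale estimate.
#' @export
coef_of <- function(fit, label) {
  i <- match(label, fit$estimates$parameter)
  if (is.na(i)) abort(paste0("No parameter labelled '", label, "'."))
  fit$estimates$estimate[i]
}

#' Observation-level predictions of a fit
#'
#' Returns the analysis dataset with population predictions (`pred`,
#' random effects at zero) and individual predictions (`ipred`, at the
#' conditional modes) plus the individual weighted residual `iwres`.
#'
#' @param fit A `tac_fit`.
#' @return A tibble.
#' @export
augment_fit <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  dv <- if (fit$spec$model == "mm") "daily_dose" else "c0"
  pred <- population_pred(fit$spec, fit$data)
  out <- tibble::as_tibble(fit$data)
  out$observed <- out[[dv]]
  out$pred <- pred
  out$ipred <- fit$pred_ind
  out$iwres <- (out$observed - out$ipred) / sqrt(fit$var_ind)
  out
}

#' Goodness-of-fit panels for a fitted model
#'
#' Four standard panels: observations against population and individual
#' predictions, and individual weighted residuals against individual
#' predictions and postoperative day.
#'
#' @param object A `tac_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tac_fit <- function(object, ...) {
  aug <- augment_fit(object)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "observed vs population pred",
                   x = aug$pred, y = aug$observed),
    tibble::tibble(panel = "observed vs individual pred",
                   x = aug$ipred, y = aug$observed),
    tibble::tibble(panel = "IWRES vs individual pred",
                   x = aug$ipred, y = aug$iwres),
    tibble::tibble(panel = "IWRES vs postoperative day",
                   x = aug$pod, y = aug$iwres)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(se = FALSE, method = "loess",
                         formula = y ~ x, colour = "red",
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
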