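#' Control settings for population fitting
#'
#' @param multistart total number of optimisation starts; the fit always
#'   runs its deterministic start set (pooled, two-stage and
#'   variance-pattern starts), and values above that count add seeded
#'   log-scale jitters around the primary start.
#' @param seed integer seed controlling the jittered starts; `NULL` leaves
#'   the RNG state untouched.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param max_iter maximum outer iterations per start.
#' @param omega2_fixed optional numeric vector pinning the random-effect
#'   variances (zeros give a pooled fit with all random effects at 0);
#'   `NULL` estimates them.
#' @param compute_cov whether to compute the fixed-effect covariance (and
#'   CV%) from a finite-difference Hessian of the profile objective.
#' @param jitter_sd standard deviation of the log-scale start jitter.
#' @param init optional list with elements `tvp`, `omega2`, `sigma2` used as
#'   the first start (e.g. to warm-start a refit from a previous fit).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(multistart = 10L, seed = 1L, rel_tol = 1e-8,
                        max_iter = 500L, omega2_fixed = NULL,
                        compute_cov = TRUE, jitter_sd = 0.5, init = NULL) {
  structure(list(multistart = as.integer(multistart), seed = seed,
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 omega2_fixed = omega2_fixed, compute_cov = compute_cov,
                 jitter_sd = jitter_sd, init = init),
            class = "fit_control")
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.prep_data <- function(data) {
  ids <- patients(data)
  idx <- match(data$patient_id, ids)
  o <- order(idx, data$time_min)
  d <- data[o, , drop = FALSE]
  len <- as.integer(table(factor(d$patient_id, levels = ids)))
  list(ids = ids, M = length(ids), times = d$time_min,
       logy = log(d$activity_pct),
       start = as.integer(cumsum(c(0L, len[-length(len)]))), len = len)
}

# Unconstrained parameterisation of the fixed effects: logs of amplitudes
# and alpha (alpha capped at 1 by an upper bound), and for models with an
# ordering constraint the slowest rate plus log-increments between
# successive rates (removes label switching from the search space).
.par_codec <- function(model) {
  model <- soe_model(model)
  pn <- model$param_names
  lam <- grep("^lambda", pn)
  lower <- rep(log(1e-6), length(pn))
  upper <- rep(log(1e7), length(pn))
  lower[lam] <- log(1e-8)
  upper[lam] <- log(10)
  if (!is.na(model$alpha_param)) upper[pn == model$alpha_param] <- 0
  if (model$ordered && length(lam) > 1) {
    encode <- function(tvp) {
      x <- log(tvp)
      x[lam[-1]] <- log(diff(tvp[lam]))
      x
    }
    decode <- function(par) {
      tvp <- exp(par)
      tvp[lam] <- cumsum(tvp[lam])
      tvp
    }
  } else {
    encode <- function(tvp) log(tvp)
    decode <- function(par) exp(par)
  }
  list(encode = encode, decode = decode, lower = lower, upper = upper)
}

# Deterministic variants of a base start: fractional contributions swept
# over a coarse grid and the fast/slow rate ratio varied; catches the main
# basins of the multimodal likelihood before any random jitter.
.start_grid <- function(model, tvp0) {
  out <- list(tvp0)
  if (!is.na(model$alpha_param)) {
    for (a in c(0.25, 0.5, 0.75)) {
      t <- tvp0
      t[model$alpha_param] <- a
      out <- c(out, list(t))
    }
  }
  if ("lambda2" %in% model$param_names) {
    for (r in c(3, 30)) {
      t <- tvp0
      t["lambda2"] <- t["lambda1"] * r
      if (model$id == "f5a") t["lambda3"] <- t["lambda2"] * r
      out <- c(out, list(t))
    }
  }
  out
}

# Two-stage initialisation: individual (per-patient) least-squares fits
# around the pooled solution give a typical value as the geometric mean of
# the individual estimates and random-effect variance starts as the
# empirical variances of their logs.  Adapts the variance starts to the
# actual inter-patient spread (which can be large for the fast rate).
.twostage_start <- function(model, tvp0, codec, prep, constants) {
  p <- model$n_params
  one <- function(m, tvp_start) {
    a <- prep$start[m] + 1L
    b <- prep$start[m] + prep$len[m]
    obj <- function(par) {
      tvp <- codec$decode(par)
      if (any(!is.finite(tvp))) return(1e10)
      r <- cpp_laplace_ofv(model$code, tvp, rep(0, p), 1,
                           prep$times[a:b], prep$logy[a:b], 0L,
                           prep$len[m], matrix(0, 0, 0),
                           constants$lambda_phys, constants$lambda_bc)
      if (!isTRUE(r$ok) || !is.finite(r$ofv)) 1e10 else r$ofv
    }
    s <- pmin(pmax(codec$encode(tvp_start), codec$lower + 1e-9),
              codec$upper - 1e-9)
    run <- tryCatch(
      stats::nlminb(s, obj, lower = codec$lower, upper = codec$upper,
                    control = list(rel.tol = 1e-8, iter.max = 200L)),
      error = function(e) NULL)
    if (is.null(run) || !is.finite(run$objective) || run$objective >= 1e10) {
      return(list(par = tvp_start, ssr = NA_real_, n = prep$len[m]))
    }
    list(par = codec$decode(run$par),
         ssr = run$objective - prep$len[m] * log(2 * pi), n = prep$len[m])
  }
  M <- length(prep$len)
  ind <- lapply(seq_len(M), one, tvp_start = tvp0)
  # clamp individual estimates to +/- 3 log units around the pooled values
  lp <- vapply(ind, function(x) {
    pmin(pmax(log(x$par), log(tvp0) - 3), log(tvp0) + 3)
  }, numeric(p))
  tvp <- exp(rowMeans(lp))
  names(tvp) <- model$param_names
  if (!is.na(model$alpha_param)) {
    tvp[model$alpha_param] <- min(max(tvp[model$alpha_param], 0.02), 0.98)
  }
  om <- pmin(pmax(apply(lp, 1, stats::var), 1e-3), 1.5)
  ssr <- vapply(ind, function(x) x$ssr, numeric(1))
  n <- vapply(ind, function(x) x$n, numeric(1))
  s2 <- sum(ssr[is.finite(ssr)]) / sum(n[is.finite(ssr)])
  if (!is.finite(s2) || s2 <= 1e-4) s2 <- 0.03
  list(tvp = tvp, omega2 = om, sigma2 = min(s2, 1))
}

.pooled_start <- function(model, data, tvp0, codec, prep, constants) {
  obj <- function(par) {
    tvp <- codec$decode(par[seq_len(model$n_params)])
    if (any(!is.finite(tvp))) return(1e10)
    r <- cpp_laplace_ofv(model$code, tvp, rep(0, model$n_params),
                         exp(par[model$n_params + 1L]),
                         prep$times, prep$logy, prep$start, prep$len,
                         matrix(0, 0, 0), constants$lambda_phys,
                         constants$lambda_bc)
    if (!isTRUE(r$ok) || !is.finite(r$ofv)) 1e10 else r$ofv
  }
  lower <- c(codec$lower, log(1e-8))
  upper <- c(codec$upper, log(10))
  best <- tvp0
  best_val <- Inf
  for (tvp in .start_grid(model, tvp0)) {
    s <- pmin(pmax(c(codec$encode(tvp), log(0.05)), lower + 1e-9),
              upper - 1e-9)
    if (obj(s) >= 1e10) next
    run <- tryCatch(
      stats::nlminb(s, obj, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-8, iter.max = 300L)),
      error = function(e) NULL)
    if (!is.null(run) && is.finite(run$objective) &&
        run$objective < best_val) {
      best_val <- run$objective
      best <- codec$decode(run$par[seq_len(model$n_params)])
    }
  }
  names(best) <- model$param_names
  best
}

# Data-driven starting values: terminal slope for the slow rate, peak
# activity for amplitudes, trapezoid-plus-tail integral for TIA-scaled
# amplitudes.
.start_tvp <- function(model, data, constants) {
  model <- soe_model(model)
  lp <- constants$lambda_phys
  late <- data[data$time_min > 600, , drop = FALSE]
  if (nrow(late) >= 3) {
    sl <- stats::coef(stats::lm(log(activity_pct) ~ time_min, data = late))[2]
    lam_term <- max(-as.numeric(sl), 2e-5)
  } else lam_term <- 3e-4
  peak <- max(data$activity_pct)
  tia <- mean(vapply(.split_patients(data), function(d) {
    o <- order(d$time_min)
    t <- d$time_min[o]; y <- d$activity_pct[o]
    sum(diff(t) * (y[-1] + y[-length(y)]) / 2) + y[1] * t[1] / 2 +
      y[length(y)] / lam_term
  }, numeric(1)))
  l1 <- max(lam_term - lp, 2e-5)
  switch(model$id,
    f3a = c(A1 = 1.3 * peak, lambda1 = l1, lambda2 = 20 * l1),
    f3b = c(A1 = 1 / tia, lambda1 = l1, lambda2 = 20 * l1),
    f3c = c(A1 = tia, lambda1 = l1, lambda2 = 20 * l1),
    f3d = c(A1 = 1 / tia, lambda1 = lam_term, lambda2 = 20 * lam_term),
    f4a = c(A1 = 1.2 * peak, A2 = 0.5 * peak, lambda1 = l1, lambda2 = 15 * l1),
    f4b = c(A1 = 1.8 * peak, alpha = 0.65, lambda1 = l1, lambda2 = 15 * l1),
    f4c = c(A1 = 1.8 * peak, alpha = 0.35, lambda1 = l1, lambda2 = 15 * l1),
    f4d = c(A1 = tia, alpha = 0.3, lambda1 = l1, lambda2 = 6 * l1),
    f4e = c(A1 = tia, alpha = 0.7, lambda1 = l1, lambda2 = 6 * l1),
    f5a = c(A1 = 1.3 * peak, A2 = 0.4 * peak, lambda1 = l1,
            lambda2 = 10 * l1, lambda3 = 100 * l1),
    f5b = c(A1 = peak, A2 = 0.1 * peak, A3 = 0.5 * peak,
            lambda1 = l1, lambda2 = 15 * l1)
  )
}

#' Fit a nonlinear mixed-effects population model
#'
#' Maximises the Laplace-approximated marginal likelihood of a
#' sum-of-exponential model over the fixed effects (typical parameter
#' values, TVP), the diagonal log-normal random-effect variances and the
#' residual variance of the log-scale (exponential) error model.  Individual
#' parameters combine multiplicatively, `P_j = TVP_j * exp(ETA_j)` with
#' `ETA_j ~ N(0, omega2_j)`, and the per-patient modes (empirical-Bayes
#' estimates) are re-optimised inside every outer objective evaluation.
#'
#' @param data a [biokinetics()] dataset with at least two patients.
#' @param model model id or [soe_model()].
#' @param control a [fit_control()] list.
#' @param constants a [decay_constants()] object.
#' @return An object of class `pop_fit` with the fixed effects (`tvp`),
#'   random-effect variances (`omega2`), residual variance (`sigma2`), the
#'   objective value `ofv` (-2 log marginal likelihood), per-patient
#'   empirical-Bayes random effects (`etas`) and individual parameters,
#'   the fixed-effect covariance and CV%, and a convergence flag.
#' @export
fit_population <- function(data, model, control = fit_control(),
                           constants = decay_constants()) {
  model <- soe_model(model)
  if (!inherits(data, "biokinetics")) {
    data <- biokinetics(data$patient_id, time_min = data$time_min,
                        activity_pct = data$activity_pct)
  }
  prep <- .prep_data(data)
  if (prep$M < 2) {
    stop("population fitting requires at least 2 patients", call. = FALSE)
  }
  p <- model$n_params
  codec <- .par_codec(model)
  est_omega <- is.null(control$omega2_fixed)
  if (!est_omega && length(control$omega2_fixed) == 1L) {
    control$omega2_fixed <- rep(control$omega2_fixed, p)
  }

  decode_full <- function(par) {
    tvp <- codec$decode(par[seq_len(p)])
    if (est_omega) {
      list(tvp = tvp, omega2 = exp(par[(p + 1):(2 * p)]),
           sigma2 = exp(par[2 * p + 1]))
    } else {
      list(tvp = tvp, omega2 = control$omega2_fixed, sigma2 = exp(par[p + 1]))
    }
  }
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, p, prep$M)
  obj <- function(par) {
    th <- decode_full(par)
    if (any(!is.finite(th$tvp))) return(1e10)
    res <- cpp_laplace_ofv(model$code, th$tvp, th$omega2, th$sigma2,
                           prep$times, prep$logy, prep$start, prep$len,
                           env$eta, constants$lambda_phys, constants$lambda_bc)
    if (!isTRUE(res$ok) || !is.finite(res$ofv)) return(1e10)
    env$eta <- res$etas
    res$ofv
  }

  # bounds and starts
  if (est_omega) {
    lower <- c(codec$lower, rep(log(1e-6), p), log(1e-8))
    upper <- c(codec$upper, rep(log(25), p), log(10))
  } else {
    lower <- c(codec$lower, log(1e-8))
    upper <- c(codec$upper, log(10))
  }
  clamp <- function(x) pmin(pmax(x, lower + 1e-9), upper - 1e-9)
  if (!is.null(control$init)) {
    tvp0 <- .soe_param_vector(model, control$init$tvp)
    s20 <- max(control$init$sigma2 %||% 0.05, 2e-8)
    if (est_omega) {
      w0 <- pmax(control$init$omega2 %||% rep(0.1, p), 2e-6)
      starts <- list(clamp(c(codec$encode(tvp0), log(w0), log(s20))))
    } else {
      starts <- list(clamp(c(codec$encode(tvp0), log(s20))))
    }
  } else {
    # pooled pre-fit over a deterministic grid of shape starts, then
    # two-stage (individual-fit) starts for the variance components
    tvp0 <- .pooled_start(model, data, .start_tvp(model, data, constants),
                          codec, prep, constants)
    if (est_omega) {
      ts <- .twostage_start(model, tvp0, codec, prep, constants)
      triples <- list(list(ts$tvp, ts$omega2, ts$sigma2),
                      list(tvp0, ts$omega2, ts$sigma2),
                      list(ts$tvp, rep(0.1, p), 0.05),
                      list(tvp0, rep(0.1, p), 0.05))
      # boundary optima with one vanishing random-effect variance are
      # easily missed from interior starts: one near-zero pattern each,
      # crossed with both fixed-effect start vectors
      for (j in seq_len(p)) {
        w <- rep(0.1, p)
        w[j] <- 1e-4
        triples <- c(triples, list(list(ts$tvp, w, 0.05)),
                     list(list(tvp0, w, 0.05)))
      }
      starts <- lapply(triples, function(tr) {
        clamp(c(codec$encode(tr[[1]]), log(tr[[2]]), log(tr[[3]])))
      })
      tvp0 <- ts$tvp
    } else {
      starts <- list(clamp(c(codec$encode(tvp0), log(0.05))))
    }
  }
  # multistart counts extra jittered starts on top of the deterministic ones
  nstart <- max(1L, control$multistart)
  if (nstart > length(starts)) {
    par0 <- starts[[1]]
    starts <- c(starts, .with_seed(control$seed, {
      replicate(nstart - length(starts), {
        clamp(par0 + stats::rnorm(length(par0), 0, control$jitter_sd))
      }, simplify = FALSE)
    }))
  }

  best <- NULL
  for (s in starts) {
    if (obj(s) >= 1e10) next
    run <- tryCatch(
      stats::nlminb(s, obj, lower = lower, upper = upper,
                    control = list(rel.tol = control$rel_tol,
                                   iter.max = control$max_iter,
                                   eval.max = 4L * control$max_iter)),
      error = function(e) NULL)
    if (is.null(run) || !is.finite(run$objective) || run$objective >= 1e10)
      next
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (is.null(best)) {
    return(structure(list(model = model, converged = FALSE, ofv = Inf,
                          data = data, control = control,
                          constants = constants, n_obs = nrow(data),
                          patients = prep$ids),
                     class = "pop_fit"))
  }
  for (i in 1:3) { # polish until the restart no longer improves
    polish <- tryCatch(
      stats::nlminb(best$par, obj, lower = lower, upper = upper,
                    control = list(rel.tol = control$rel_tol * 0.01,
                                   iter.max = control$max_iter,
                                   eval.max = 4L * control$max_iter)),
      error = function(e) NULL)
    if (is.null(polish) || !is.finite(polish$objective) ||
        polish$objective > best$objective) break
    gain <- best$objective - polish$objective
    best <- polish
    if (gain < 1e-6) break
  }

  th <- decode_full(best$par)
  names(th$tvp) <- model$param_names
  names(th$omega2) <- model$param_names
  th$sigma2 <- unname(th$sigma2)
  final <- cpp_laplace_ofv(model$code, th$tvp, th$omega2, th$sigma2,
                           prep$times, prep$logy, prep$start, prep$len,
                           env$eta, constants$lambda_phys,
                           constants$lambda_bc)
  etas <- final$etas
  dimnames(etas) <- list(model$param_names, prep$ids)
  ind <- th$tvp * exp(etas) # p x M matrix of individual parameters

  cov_tvp <- NULL
  cv <- rep(NA_real_, p)
  if (isTRUE(control$compute_cov)) {
    # profile objective in log fixed-effect coordinates: uniformly
    # conditioned steps, positivity preserved, and a solution at a
    # constraint boundary shows up as an infeasible perturbation
    prof <- function(lt) {
      r <- cpp_laplace_ofv(model$code, exp(lt), th$omega2, th$sigma2,
                           prep$times, prep$logy, prep$start, prep$len,
                           env$eta, constants$lambda_phys,
                           constants$lambda_bc)
      if (!isTRUE(r$ok) || !is.finite(r$ofv)) 1e10 else r$ofv
    }
    hh <- .fd_hessian(prof, log(unname(th$tvp)), h = 0.02)
    cov_log <- if (hh$ok) {
      tryCatch(2 * solve(hh$H), error = function(e) NULL)
    }
    if (!is.null(cov_log) && all(is.finite(cov_log)) &&
        all(diag(cov_log) > 0)) {
      # delta method: CV of a positive parameter is the SD of its log
      cv <- 100 * sqrt(diag(cov_log))
      cov_tvp <- diag(th$tvp, p) %*% cov_log %*% diag(th$tvp, p)
      dimnames(cov_tvp) <- list(model$param_names, model$param_names)
    } else {
      cv <- rep(Inf, p) # singular or boundary information
    }
  }
  names(cv) <- model$param_names

  structure(list(model = model, tvp = th$tvp, omega2 = th$omega2,
                 sigma2 = th$sigma2, ofv = best$objective, etas = etas,
                 individual = ind, cov_tvp = cov_tvp, cv_percent = cv,
                 converged = best$convergence == 0 ||
                   grepl("convergence", best$message %||% ""),
                 message = best$message, n_obs = nrow(data),
                 patients = prep$ids, data = data, control = control,
                 constants = constants),
            class = "pop_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central-difference Hessian with uniform absolute step; ok is FALSE when
# any evaluation hit an infeasible point
.fd_hessian <- function(f, x, h = 0.02) {
  n <- length(x)
  bad <- FALSE
  fc <- function(y) {
    v <- f(y)
    if (!is.finite(v) || v >= 1e9) bad <<- TRUE
    v
  }
  f0 <- fc(x)
  H <- matrix(NA_real_, n, n)
  step <- function(i, s) { y <- x; y[i] <- y[i] + s * h; y }
  for (i in seq_len(n)) {
    H[i, i] <- (fc(step(i, 1)) - 2 * f0 + fc(step(i, -1))) / h^2
    if (i < n) for (j in (i + 1):n) {
      y1 <- step(i, 1); y1[j] <- y1[j] + h
      y2 <- step(i, 1); y2[j] <- y2[j] - h
      y3 <- step(i, -1); y3[j] <- y3[j] + h
      y4 <- step(i, -1); y4[j] <- y4[j] - h
      H[i, j] <- H[j, i] <- (fc(y1) - fc(y2) - fc(y3) + fc(y4)) / (4 * h^2)
    }
  }
  list(H = H, ok = !bad)
}

#' @export
print.pop_fit <- function(x, ...) {
  cat("Population NLME fit, model ", x$model$id, "\n", sep = "")
  if (!isTRUE(x$converged)) cat("  ** fit did not converge **\n")
  cat("  patients: ", length(x$patients), ", observations: ", x$n_obs,
      "\n  OFV (-2 log marginal likelihood): ",
      format(x$ofv, digits = 8), "\n", sep = "")
  if (!is.null(x$tvp)) {
    tab <- data.frame(`fixed effect` = signif(x$tvp, 4),
                      `CV%` = round(x$cv_percent, 1),
                      `omega^2` = signif(x$omega2, 3),
                      check.names = FALSE)
    print(tab)
    cat("  residual variance (log scale): ", signif(x$sigma2, 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Joint (inner) objective of the Laplace scheme
#'
#' Computes the joint -2 log of the Gaussian log-residual likelihood and the
#' Gaussian random-effect priors at given population parameters and random
#' effects: the quantity whose per-patient minimisation over `eta` defines
#' the empirical-Bayes estimates.  Random effects with `omega2 = 0` are
#' pinned at 0 and contribute no prior term; a non-zero `eta` for such a
#' component, or a non-positive model prediction at an observation time,
#' gives `Inf`.
#'
#' @param model model id or [soe_model()].
#' @param tvp fixed effects (typical values), in model parameter order.
#' @param omega2 random-effect variances (same order).
#' @param sigma2 residual variance of the log-scale error.
#' @param etas matrix of random effects, parameters x patients (a vector is
#'   recycled as a single column).
#' @param data a [biokinetics()] dataset whose patients match `etas` columns.
#' @param constants a [decay_constants()] object.
#' @return The joint -2 log likelihood (scalar).
#' @export
joint_objective <- function(model, tvp, omega2, sigma2, etas, data,
                            constants = decay_constants()) {
  model <- soe_model(model)
  p <- model$n_params
  if (is.vector(etas)) etas <- matrix(etas, nrow = p)
  ids <- patients(data)
  stopifnot(ncol(etas) == length(ids), sigma2 > 0, length(omega2) == p)
  total <- 0
  for (m in seq_along(ids)) {
    d <- data[data$patient_id == ids[m], , drop = FALSE]
    eta <- etas[, m]
    if (any(omega2 == 0 & eta != 0)) return(Inf)
    P <- tvp * exp(eta)
    names(P) <- model$param_names
    pred <- cpp_soe_eval(model$code, unname(P), d$time_min,
                         constants$lambda_phys, constants$lambda_bc)
    if (any(!is.finite(pred)) || any(pred <= 0)) return(Inf)
    r <- log(d$activity_pct) - log(pred)
    total <- total + sum(r^2) / sigma2 + nrow(d) * log(2 * pi * sigma2)
    free <- omega2 > 0
    total <- total + sum(eta[free]^2 / omega2[free]) +
      sum(log(2 * pi * omega2[free]))
  }
  total
}

#' Empirical-Bayes individual estimate
#'
#' Posterior-mode (MAP) random effects for one patient given the population
#' parameters of a converged fit.  With no observations the prior mode
#' `eta = 0` is returned (full shrinkage to the population-typical values).
#'
#' @param fit a converged [fit_population()] result.
#' @param newdata observations of a single patient: a data.frame with
#'   columns `time_min` and `activity_pct` (or a [biokinetics()] subset);
#'   may have zero rows.
#' @return A list with `eta` (named random-effect vector) and `params`
#'   (individual parameters `TVP * exp(eta)`).
#' @export
empirical_bayes <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "pop_fit"), isTRUE(fit$converged))
  p <- fit$model$n_params
  if (is.null(newdata) || nrow(newdata) == 0L) {
    eta <- stats::setNames(rep(0, p), fit$model$param_names)
    return(list(eta = eta, params = fit$tvp))
  }
  res <- cpp_inner_map(fit$model$code, unname(fit$tvp), unname(fit$omega2),
                       fit$sigma2, newdata$time_min,
                       log(newdata$activity_pct), rep(0, p),
                       fit$constants$lambda_phys, fit$constants$lambda_bc)
  if (!isTRUE(res$ok)) {
    stop("empirical-Bayes optimisation failed for the supplied observations",
         call. = FALSE)
  }
  eta <- stats::setNames(as.numeric(res$eta), fit$model$param_names)
  list(eta = eta, params = fit$tvp * exp(eta))
}

#' Individual parameters of a fitted patient
#' @param fit a [fit_population()] result.
#' @param patient_id one of `fit$patients`.
#' @return Named vector of the patient's empirical-Bayes parameters.
#' @export
individual_params <- function(fit, patient_id) {
  if (!patient_id %in% fit$patients) {
    stop("unknown patient: ", patient_id, call. = FALSE)
  }
  fit$individual[, patient_id]
}

#' Predict an individual time-activity curve
#'
#' @param fit a [fit_population()] result.
#' @param patient_id one of `fit$patients`.
#' @param times times in minutes post injection.
#' @return Predicted activities (% administered).
#' @export
predict_curve <- function(fit, patient_id, times) {
  soe_eval(fit$model, individual_params(fit, patient_id), times,
           fit$constants)
}
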