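test_that("the joint objective reduces to its Gaussian constants at zero residual", {
  p <- table2_params()
  times <- c(180, 280, 1370, 2800, 4250)
  y <- soe_eval("f4d", p, times)
  d <- biokinetics(rep("P1", 5), time_min = times, activity_pct = y)
  s2 <- 0.04
  o <- joint_objective("f4d", p, omega2 = rep(0, 4), sigma2 = s2,
                       etas = rep(0, 4), data = d)
  expect_equal(o, 5 * log(2 * pi * s2))
  # doubling sigma2 with zero residuals adds N log 2
  o2 <- joint_objective("f4d", p, rep(0, 4), 2 * s2, rep(0, 4), d)
  expect_equal(o2 - o, 5 * log(2))
  # non-zero eta on a pinned (omega2 = 0) effect is inadmissible
  expect_identical(joint_objective("f4d", p, rep(0, 4), s2,
                                   c(0.1, 0, 0, 0), d), Inf)
  # a free effect contributes its prior terms
  o3 <- joint_objective("f4d", p, c(0.5, 0, 0, 0), s2, rep(0, 4), d)
  expect_equal(o3 - o, log(2 * pi * 0.5))
})

test_that("empirical-Bayes estimates match a grid-search oracle in 1-D", {
  fit <- structure(list(
    model = soe_model("f4d"),
    tvp = table2_params(),
    omega2 = c(A1 = 0.25, alpha = 0, lambda1 = 0, lambda2 = 0),
    sigma2 = 0.04, constants = decay_constants(), converged = TRUE
  ), class = "pop_fit")
  obs <- data.frame(time_min = 1370,
                    activity_pct = 1.6 * soe_eval("f4d", fit$tvp, 1370))
  d1 <- biokinetics("P1", time_min = obs$time_min,
                    activity_pct = obs$activity_pct)
  grid <- seq(-1.5, 1.5, by = 1e-4)
  vals <- vapply(grid, function(e) {
    joint_objective("f4d", fit$tvp, fit$omega2, fit$sigma2,
                    c(e, 0, 0, 0), d1)
  }, numeric(1))
  oracle_eta <- grid[which.min(vals)]
  eb <- empirical_bayes(fit, obs)
  expect_equal(unname(eb$eta[["A1"]]), oracle_eta, tolerance = 1e-3)
  expect_identical(unname(eb$eta[c("alpha", "lambda1", "lambda2")]),
                   c(0, 0, 0))
  # shrinkage: the MAP lies between prior mode and data mode
  expect_gt(oracle_eta, 0)
  expect_lt(oracle_eta, log(1.6))
})

test_that("Laplace marginal equals the exact integral for log-linear effects", {
  # random effect on the amplitude enters the log-residual linearly, so the
  # marginal likelihood is Gaussian and the Laplace approximation is exact
  p <- c(A1 = 120, lambda1 = 1.6e-4, lambda2 = 1.2e-3)
  om <- c(0.3, 0, 0)
  s2 <- 0.04
  cc <- decay_constants()
  set.seed(88)
  times <- list(c(170, 1400, 2800), c(200, 1300, 4200))
  ys <- lapply(times, function(t) {
    soe_eval("f3c", p, t) * exp(stats::rnorm(length(t), 0.2, 0.25))
  })
  exact <- 0
  for (m in 1:2) {
    ci <- log(ys[[m]]) - log(soe_eval("f3c", p, times[[m]]))
    n <- length(ci)
    lik <- stats::integrate(function(eta) {
      vapply(eta, function(e) {
        (2 * pi * s2)^(-n / 2) * exp(-sum((ci - e)^2) / (2 * s2)) *
          stats::dnorm(e, 0, sqrt(om[1]))
      }, numeric(1))
    }, -10, 10, rel.tol = 1e-12)$value
    exact <- exact - 2 * log(lik)
  }
  d <- biokinetics(rep(c("P1", "P2"), each = 3),
                   time_min = unlist(times), activity_pct = unlist(ys))
  prep <- msnlme:::.prep_data(d)
  got <- msnlme:::cpp_laplace_ofv(soe_model("f3c")$code, unname(p), om, s2,
                                  prep$times, prep$logy, prep$start,
                                  prep$len, matrix(0, 3, 2),
                                  cc$lambda_phys, cc$lambda_bc)
  expect_true(got$ok)
  expect_equal(got$ofv, exact, tolerance = 1e-6)
})

test_that("with variances pinned at zero the fit is pooled least squares", {
  co <- default_cohort()
  fit <- fit_population(co$data, "f3c",
                        fit_control(multistart = 2, seed = 1,
                                    omega2_fixed = 0, compute_cov = FALSE))
  expect_true(fit$converged)
  expect_true(all(fit$etas == 0))
  ssr <- function(lp) {
    pr <- soe_eval("f3c", c(A1 = exp(lp[1]), lambda1 = exp(lp[2]),
                            lambda2 = exp(lp[2]) + exp(lp[3])),
                   co$data$time_min)
    if (any(pr <= 0)) return(1e10)
    sum((log(co$data$activity_pct) - log(pr))^2)
  }
  # independent pooled NLS oracle on the same log-residuals
  o <- stats::optim(c(log(130), log(1.5e-4), log(7e-4)), ssr,
                    method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, ssr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  oracle_tvp <- c(exp(o$par[1]), exp(o$par[2]), exp(o$par[2]) + exp(o$par[3]))
  expect_equal(unname(fit$tvp), oracle_tvp, tolerance = 1e-3)
  # and the profiled residual variance is the mean squared residual
  expect_equal(fit$sigma2,
               ssr(log(unname(c(fit$tvp[1], fit$tvp[2],
                                fit$tvp[3] - fit$tvp[2])))) / 40,
               tolerance = 1e-4)
})

test_that("population fitting needs at least two patients", {
  co <- default_cohort()
  one <- co$data[co$data$patient_id == "P1", , drop = FALSE]
  expect_error(fit_population(one, "f4d", fast_ctl()), "2 patients")
})

test_that("empirical-Bayes estimates shrink to the prior without data", {
  fit <- cached_fit("f4d")
  eb0 <- empirical_bayes(fit, NULL)
  expect_identical(unname(eb0$eta), rep(0, 4))
  expect_identical(eb0$params, fit$tvp)
  # near-degenerate prior pins the individual at the typical values
  tight <- fit
  tight$omega2 <- rep(1e-10, 4)
  obs <- fit$data[fit$data$patient_id == "P3", ]
  ebt <- empirical_bayes(tight, obs)
  expect_equal(unname(ebt$params), unname(fit$tvp), tolerance = 1e-3)
})

test_that("random effects shrink toward zero as observations are removed", {
  fit <- cached_fit("f4d")
  co <- default_cohort()
  norms <- vapply(c(5L, 1L), function(k) {
    mean(vapply(fit$patients, function(m) {
      obs <- co$data[co$data$patient_id == m, , drop = FALSE]
      obs <- obs[seq_len(k), , drop = FALSE]
      sqrt(sum(empirical_bayes(fit, obs)$eta^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("individual curve predictions start at zero and follow the model", {
  fit <- cached_fit("f4d")
  m <- fit$patients[1]
  expect_identical(predict_curve(fit, m, 0), 0)
  ts <- c(200, 1400, 3000)
  expect_equal(predict_curve(fit, m, ts),
               soe_eval("f4d", individual_params(fit, m), ts))
  expect_error(predict_curve(fit, "ghost", 100), "unknown")
})
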