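test_that("quadrature TIA matches the closed form on the fitted scale", {
  p <- table2_params()
  expect_equal(tia_numeric("f4d", p), 129.36, tolerance = 1e-3)
  # truncation at 100,000 min loses < 1e-3 of the infinite-horizon integral
  expect_lt(abs(tia_numeric("f4d", p) - soe_tia("f4d", p)) /
              soe_tia("f4d", p), 1e-3)
  set.seed(33)
  for (id in c("f3a", "f3d", "f4b", "f5a")) {
    q <- random_params(id, 1L)[[1]]
    expect_equal(tia_numeric(id, q, t_end = 1e7), soe_tia(id, q),
                 tolerance = 1e-4, info = id)
  }
  expect_identical(tia_numeric("f3a", c(A1 = 0, lambda1 = 1e-4,
                                        lambda2 = 1e-3)), 0)
})

test_that("relative deviation is the signed fractional error", {
  expect_identical(relative_deviation(100, 100), 0)
  expect_equal(relative_deviation(110, 100), 0.1)
  expect_equal(relative_deviation(90, 100), -0.1)
  expect_error(relative_deviation(1, 0), "zero")
})

test_that("RMSE combines mean and spread of the relative deviations", {
  expect_equal(rd_rmse(c(0.1, -0.1))$rmse, 0.1)
  expect_equal(rd_rmse(rep(0.07, 5))$rmse, 0.07)
  expect_equal(rd_rmse(c(0.03, 0.04))$rmse, 0.035355339, tolerance = 1e-8)
  expect_error(rd_rmse(numeric(0)), "empty")
  # population-SD convention makes RMSE the literal root mean square
  set.seed(5)
  for (i in 1:10) {
    rds <- stats::rnorm(sample(2:10, 1), sd = 0.1)
    rep_ <- rd_rmse(rds)
    expect_equal(rep_$rmse, sqrt(mean(rds^2)))
    expect_gte(rep_$rmse, abs(rep_$mean_rd))
    expect_gte(rep_$rmse, rep_$sd_rd)
  }
  # sample-SD convention is larger for finite n
  rds <- c(0.02, -0.05, 0.01)
  expect_gt(rd_rmse(rds, sd_type = "sample")$rmse, rd_rmse(rds)$rmse)
})

test_that("ATP reference TIAs integrate each patient's individual curve", {
  fit <- cached_fit("f4d")
  atp <- atp_reference_tias(fit)
  expect_identical(atp$patient_id, fit$patients)
  expect_true(all(atp$tia > 0))
  expect_identical(unique(atp$method), "ATP")
  m <- fit$patients[3]
  expect_identical(atp$tia[3], tia_numeric(fit$model,
                                           individual_params(fit, m)))
})

test_that("STP with the target's full data reproduces the ATP TIA", {
  co <- default_cohort()
  fit <- cached_fit("f4d")
  atp <- atp_reference_tias(fit)
  for (m in fit$patients[c(1, 5)]) {
    stp <- stp_tia(co$data, m, "f4d", all_points = TRUE, mode = "refit",
                   control = fast_ctl(), atp_fit = fit)
    ref <- atp$tia[atp$patient_id == m]
    expect_lt(abs(stp$tia - ref) / ref, 0.01)
  }
})

test_that("frozen-population STP agrees with the joint refit to a few percent", {
  co <- default_cohort()
  fit <- cached_fit("f4d")
  m <- fit$patients[2]
  # this patient's T4 session was drawn just outside the 3 h window, so
  # the schedule-tolerance warning must fire
  expect_warning(
    s1 <- stp_tia(co$data, m, "f4d", time_label = "T4", mode = "refit",
                  control = fast_ctl(), atp_fit = fit),
    "nominal T4")
  s2 <- suppressWarnings(
    stp_tia(co$data, m, "f4d", time_label = "T4", mode = "frozen",
            atp_fit = fit))
  expect_identical(s1$stp_time_label, "T4")
  expect_lt(abs(s1$tia - s2$tia) / s2$tia, 0.1)
})

test_that("STP shrinks the cohort TIA dispersion below the true spread", {
  co <- default_cohort()
  fit <- cached_fit("f4d")
  stp <- suppressWarnings(
    stp_cohort_tias(co$data, "f4d", time_label = "T4", mode = "frozen",
                    atp_fit = fit))
  expect_identical(nrow(stp), 8L)
  expect_lte(stats::sd(log(stp$tia)), stats::sd(log(co$true_tias)))
})

test_that("degenerate STP inputs are rejected", {
  co <- default_cohort()
  one <- co$data[co$data$patient_id == "P1", , drop = FALSE]
  expect_error(stp_tia(one, "P1", "f4d", control = fast_ctl()),
               "no population data")
  expect_error(stp_tia(co$data, "nobody", "f4d", control = fast_ctl()),
               "no observations")
})
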