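test_that("decay constants match the nuclide and blood-circulation rates", {
  cc <- decay_constants()
  expect_equal(signif(cc$lambda_phys, 3), 1.72e-4)
  expect_identical(cc$lambda_bc, log(2))
  expect_lt(decay_constants(half_life_days = 6.647)$lambda_phys,
            cc$lambda_phys) # longer-lived nuclide decays more slowly
})

test_that("rates convert to the reported biological half-lives", {
  expect_equal(signif(half_life_hours(1.5e-4), 3), 77.0)
  expect_equal(signif(half_life_hours(8.8e-4), 3), 13.1)
  expect_equal(half_life_hours(log(2)), 1 / 60)
  expect_error(half_life_hours(0), "positive")
  expect_error(half_life_hours(-1e-4), "positive")
})

test_that("the registry exposes eleven models with consistent bookkeeping", {
  ids <- soe_model_ids()
  expect_length(ids, 11L)
  for (id in ids) {
    m <- soe_model(id)
    expect_identical(m$n_params, as.integer(substr(id, 2, 2)))
    expect_identical(anyDuplicated(m$param_names), 0L)
  }
  expect_error(soe_model("f9z"), "unknown")
})

test_that("every model evaluates to exactly zero at t = 0", {
  set.seed(101)
  for (id in soe_model_ids()) {
    for (p in random_params(id, n = 5L)) {
      expect_identical(soe_eval(id, p, 0), 0,
                       info = paste(id, paste(signif(p, 3), collapse = ",")))
    }
  }
})

test_that("f4e is the alpha -> 1 - alpha reparameterisation of f4d", {
  set.seed(7)
  ts <- c(60, 1440, 4320)
  for (i in 1:10) {
    p <- random_params("f4d", 1L)[[1]]
    pe <- p
    pe["alpha"] <- 1 - p["alpha"]
    a <- soe_eval("f4d", p, ts)
    b <- soe_eval("f4e", pe, ts)
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-300)), 1e-12)
    expect_equal(soe_tia("f4e", pe), soe_tia("f4d", p), tolerance = 1e-12)
  }
  # same for the amplitude-parameterised pair f4b / f4c
  p <- c(A1 = 50, alpha = 0.3, lambda1 = 2e-4, lambda2 = 2e-3)
  pb <- p
  pb["alpha"] <- 0.7
  expect_equal(soe_eval("f4c", p, ts), soe_eval("f4b", pb, ts),
               tolerance = 1e-12)
})

test_that("a vanishing fast term leaves pure physical decay", {
  # lambda1 = 0, lambda2 large: f3a(t) ~ A1 exp(-lambda_phys t)
  val <- soe_eval("f3a", c(A1 = 1, lambda1 = 0, lambda2 = 1e3), 1440)
  expect_equal(val, exp(-decay_constants()$lambda_phys * 1440),
               tolerance = 1e-12)
})

test_that("closed-form TIAs match the quadrature oracle", {
  set.seed(202)
  for (id in soe_model_ids()) {
    for (p in random_params(id, n = 3L)) {
      analytic <- soe_tia(id, p)
      oracle <- quadrature_tia(id, p)
      expect_true(abs(analytic - oracle) / abs(oracle) < 1e-4,
                  info = paste(id, paste(signif(p, 3), collapse = ",")))
    }
  }
})

test_that("TIA-parameterised models integrate to the stated closed forms", {
  p <- table2_params()
  expect_identical(soe_tia("f4d", p), 129.36)
  pe <- p
  pe["alpha"] <- 0.69
  expect_identical(soe_tia("f4e", pe), 129.36)
  expect_equal(soe_tia("f3c", c(A1 = 42, lambda1 = 1e-4, lambda2 = 1e-3)), 42)
  expect_equal(soe_tia("f3d", c(A1 = 2, lambda1 = 1e-4, lambda2 = 1e-3)), 0.5)
  expect_equal(soe_tia("f3b", c(A1 = 4, lambda1 = 1e-4, lambda2 = 1e-3)), 0.25)
  # zero curve integrates to zero
  expect_identical(soe_tia("f3a", c(A1 = 0, lambda1 = 1e-4, lambda2 = 1e-3)), 0)
  expect_identical(soe_tia("f4b", c(A1 = 0, alpha = 0.4, lambda1 = 1e-4,
                                    lambda2 = 1e-3)), 0)
})

test_that("evaluation is homogeneous of degree 1 in the overall prefactor", {
  ts <- c(10, 300, 3000)
  for (id in c("f3a", "f3c", "f4b", "f4c", "f4d", "f4e")) {
    p <- random_params(id, 1L)[[1]]
    p2 <- p
    p2["A1"] <- 2 * p["A1"]
    expect_equal(soe_eval(id, p2, ts), 2 * soe_eval(id, p, ts),
                 tolerance = 1e-12, info = id)
  }
  # f4a and f5a scale when both prefactors are doubled
  p <- c(A1 = 10, A2 = 4, lambda1 = 2e-4, lambda2 = 2e-3)
  p2 <- p
  p2[c("A1", "A2")] <- 2 * p[c("A1", "A2")]
  expect_equal(soe_eval("f4a", p2, ts), 2 * soe_eval("f4a", p, ts),
               tolerance = 1e-12)
})

test_that("parameter validation reports bound violations", {
  expect_identical(soe_validate("f4d", table2_params()), character(0))
  bad_alpha <- table2_params()
  bad_alpha["alpha"] <- 1.2
  expect_match(soe_validate("f4d", bad_alpha), "alpha", all = FALSE)
  expect_match(soe_validate("f3a", c(A1 = 1, lambda1 = -0.1, lambda2 = 1e-3)),
               "rate", all = FALSE)
  expect_match(soe_validate("f3a", c(A1 = 1, lambda1 = 1e-3, lambda2 = 1e-4)),
               "ordering", all = FALSE)
  expect_error(soe_eval("f4d", bad_alpha, 10), "invalid")
})

test_that("degenerate equal rates are rejected where they divide by zero", {
  for (id in c("f3b", "f3c", "f3d")) {
    expect_error(soe_eval(id, c(A1 = 1, lambda1 = 1e-3, lambda2 = 1e-3), 10),
                 "degenerate", info = id)
  }
  # f3a is well-defined with equal rates (the curve vanishes)
  expect_identical(soe_eval("f3a", c(A1 = 1, lambda1 = 1e-3, lambda2 = 1e-3),
                            100), 0)
  # infinite integral: f3b/f3d with A1 = 0
  expect_error(soe_tia("f3d", c(A1 = 0, lambda1 = 1e-4, lambda2 = 1e-3)),
               "degenerate")
})
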