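test_that("NLME parameter bookkeeping is 2p + 1", {
  expect_identical(parameter_count("f3a"), 7L)
  expect_identical(parameter_count("f4d"), 9L)
  expect_identical(parameter_count("f5a"), 11L)
  for (id in soe_model_ids()) {
    expect_identical(parameter_count(id), 2L * soe_model(id)$n_params + 1L)
  }
})

test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(0, K = 9, N = 40), 24)
  expect_equal(aicc(0, K = 7, N = 40), 17.5)
  expect_equal(aicc(100, K = 9, N = 40), 124)
  expect_error(aicc(0, K = 39, N = 40), "N > K")
  # strictly increasing in K at fixed ofv and N
  ks <- c(7, 9, 11)
  expect_true(all(diff(aicc(50, ks, 40)) > 0))
})

test_that("Akaike weights normalise, order and shift-invariantly rank", {
  expect_identical(akaike_weights(3.7), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, 2 * log(3))), c(0.75, 0.25))
  set.seed(11)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:8, 1), sd = 10)
    w <- akaike_weights(a)
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
    expect_equal(w, akaike_weights(a + 123.45)) # shift invariance
    expect_identical(order(w), order(-a))       # lower AICc, higher weight
  }
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, Inf)), "non-finite")
})

fake_fit <- function(id, cv, converged = TRUE) {
  structure(list(model = soe_model(id), converged = converged,
                 cv_percent = cv, ofv = 0), class = "pop_fit")
}

test_that("the goodness-of-fit gate keys on convergence and max CV", {
  fits <- list(fake_fit("f4d", c(10.5, 7.6, 9.8, 41.4)),
               fake_fit("f4c", c(10, 51, 9, 12)),
               fake_fit("f5a", c(5, 5, 5, 5, 5), converged = FALSE),
               fake_fit("f5b", c(5, 5, Inf, 5, 5)))
  g <- goodness_of_fit_gate(fits)
  expect_identical(g$gof_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(g$max_cv_percent[1], 41.4)
  # threshold is adjustable
  expect_true(goodness_of_fit_gate(fits, cv_threshold = 60)$gof_pass[2])
})

test_that("single-candidate selection assigns weight one", {
  co <- default_cohort(seed = 7L)
  sel <- select_models(co$data, "f4d", control = fit_control(
    multistart = 2, seed = 1))
  expect_identical(nrow(sel), 1L)
  expect_equal(sel$weight, 1)
  expect_identical(sel$K, 9L)
  expect_identical(best_fit(sel)$model$id, "f4d")
})

test_that("reparameterised pair gets equal AICc and near-equal weights", {
  co <- default_cohort(seed = 7L)
  # without random effects the two parameterisations are the same model:
  # the pooled objective values must coincide
  p4d <- fit_population(co$data, "f4d",
                        fit_control(multistart = 2, seed = 1,
                                    omega2_fixed = 0, compute_cov = FALSE))
  p4e <- fit_population(co$data, "f4e",
                        fit_control(multistart = 2, seed = 1,
                                    omega2_fixed = 0, compute_cov = FALSE))
  expect_lt(abs(p4d$ofv - p4e$ofv), 1e-4)
  expect_equal(1 - p4e$tvp[["alpha"]], p4d$tvp[["alpha"]], tolerance = 5e-3)
  # with a free random effect on alpha the marginal likelihoods differ
  # only through the log-normal-on-alpha vs log-normal-on-(1-alpha)
  # prior: the fitted pair stays nearly tied
  sel <- select_models(co$data, c("f4d", "f4e"),
                       control = fit_control(multistart = 2, seed = 1))
  expect_lt(abs(diff(sel$ofv)), 0.05)
  expect_lt(abs(diff(sel$aicc)), 0.05)      # equal K, equal correction
  expect_equal(sel$weight, c(0.5, 0.5), tolerance = 0.01)
})

test_that("the jackknife produces one normalised fold per patient", {
  co <- default_cohort(seed = 7L)
  sel <- select_models(co$data, c("f4d", "f3d"),
                       control = fit_control(multistart = 2, seed = 1))
  # force both candidates regardless of full-data weights
  jk <- jackknife_weights(co$data, sel, candidates = c("f4d", "f3d"),
                          control = fast_ctl())
  expect_identical(nrow(jk$folds), 8L)
  expect_identical(jk$n_folds, 8L)
  expect_equal(unname(rowSums(jk$folds)), rep(1, 8))
  expect_true(all(jk$summary[, "min"] <= jk$summary[, "median"]))
  expect_true(all(jk$summary[, "median"] <= jk$summary[, "max"]))
  expect_error(jackknife_weights(co$data[co$data$patient_id %in%
                                           c("P1", "P2"), ], sel),
               "3 patients")
})
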