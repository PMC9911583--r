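# shared fixtures: cohorts are generated, never stored

fast_ctl <- function(...) {
  fit_control(multistart = 2L, seed = 1L, compute_cov = FALSE, ...)
}

# one default cohort reused across tests (memoised per test run)
.fixture_env <- new.env(parent = emptyenv())
default_cohort <- function(seed = 42L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(seed = seed)
  }
  .fixture_env[[key]]
}

cached_fit <- function(model = "f4d", seed = 42L, ...) {
  key <- paste0("fit_", model, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- fit_population(default_cohort(seed)$data, model,
                                          fast_ctl(...))
  }
  .fixture_env[[key]]
}

# random valid parameter sets per model, for property-style loops
random_params <- function(id, n = 1L) {
  m <- soe_model(id)
  lapply(seq_len(n), function(i) {
    lam <- sort(stats::runif(3, 1e-5, 5e-3))
    p <- c(A1 = stats::runif(1, 0.5, 200), A2 = stats::runif(1, 0.1, 100),
           A3 = stats::runif(1, 0.1, 100), alpha = stats::runif(1, 0.05, 0.95),
           lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3])
    p[m$param_names]
  })
}

table2_params <- function() {
  c(A1 = 129.36, alpha = 0.31, lambda1 = 1.5e-4, lambda2 = 8.8e-4)
}

# independent quadrature oracle for time integrals of a model curve
quadrature_tia <- function(model, params, upper = 1e7) {
  f <- function(t) soe_eval(model, params, t)
  cuts <- c(0, 50, 1e4, upper)
  sum(vapply(seq_len(length(cuts) - 1L), function(i) {
    stats::integrate(f, cuts[i], cuts[i + 1L], rel.tol = 1e-9,
                     subdivisions = 800L)$value
  }, numeric(1)))
}
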