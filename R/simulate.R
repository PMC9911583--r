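#' Study design of a virtual cohort
#'
#' Number of patients and imaging schedule.  The default emulates the study
#' conditions the analysis assumes: 8 patients imaged at five sessions with
#' nominal times (mean +/- SD, hours) T1 = 2.9 +/- 0.6, T2 = 4.6 +/- 0.4,
#' T3 = 22.8 +/- 1.6, T4 = 46.7 +/- 1.7, T5 = 70.9 +/- 1.0.
#'
#' @param n_patients number of virtual patients.
#' @param schedule data frame with columns `label`, `mean_h`, `sd_h`;
#'   means must be strictly increasing and SDs non-negative.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_patients = 8L, schedule = NULL) {
  if (is.null(schedule)) schedule <- .default_schedule()
  stopifnot(n_patients >= 1L, all(diff(schedule$mean_h) > 0),
            all(schedule$sd_h >= 0))
  structure(list(n_patients = as.integer(n_patients), schedule = schedule),
            class = "study_design")
}

#' Population ground truth for simulation
#'
#' Defaults are the population estimates of the four-parameter model `f4d`
#' on the study data: fixed effects A1 = 129.36 %.min, alpha = 0.31,
#' lambda1 = 1.5e-4 /min, lambda2 = 8.8e-4 /min; random-effect variances
#' 0.08, 0.01, 2.9e-4, 1.1; residual log-scale variance 4.4e-2.
#'
#' @param model_id generating model (default `"f4d"`).
#' @param tvp named fixed-effect vector in model parameter order.
#' @param omega2 random-effect variances (same order).
#' @param sigma2 residual variance of the log-scale error.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(model_id = "f4d",
                         tvp = c(A1 = 129.36, alpha = 0.31,
                                 lambda1 = 1.5e-4, lambda2 = 8.8e-4),
                         omega2 = c(A1 = 0.08, alpha = 0.01,
                                    lambda1 = 2.9e-4, lambda2 = 1.1),
                         sigma2 = 4.4e-2) {
  model <- soe_model(model_id)
  tvp <- .soe_param_vector(model, tvp)
  omega2 <- .soe_param_vector(model, omega2)
  stopifnot(all(omega2 >= 0), sigma2 > 0)
  bad <- soe_validate(model, tvp)
  if (length(bad)) stop("invalid truth: ", paste(bad, collapse = "; "),
                        call. = FALSE)
  structure(list(model = model, tvp = tvp, omega2 = omega2, sigma2 = sigma2),
            class = "ground_truth")
}

#' Simulate a virtual patient cohort
#'
#' Draws per-patient parameters `P_j = TVP_j * exp(ETA_j)` with
#' `ETA_j ~ N(0, omega2_j)` (the fractional-contribution parameter is
#' redrawn until it stays inside `[0, 1]`), samples each imaging time from
#' its scheduled normal distribution truncated at 0.1 h, and applies
#' multiplicative log-normal residual noise `y = f(t) * exp(eps)` with
#' `eps ~ N(0, sigma2)`.  Deterministic under a fixed seed.
#'
#' @param design a [study_design()].
#' @param truth a [ground_truth()].
#' @param seed integer seed (all randomness of the cohort flows from it);
#'   `NULL` uses the current RNG state.
#' @return List with `data` (a [biokinetics()] dataset), `params`
#'   (patients x parameters matrix of true individual values), `etas`,
#'   `true_tias` (named vector of closed-form individual TIAs), `design`,
#'   `truth` and `seed`.
#' @export
simulate_cohort <- function(design = study_design(), truth = ground_truth(),
                            seed = NULL) {
  .with_seed(seed, {
    model <- truth$model
    p <- model$n_params
    M <- design$n_patients
    ids <- sprintf("P%d", seq_len(M))
    alpha_j <- if (!is.na(model$alpha_param)) {
      which(model$param_names == model$alpha_param)
    } else 0L
    draw_eta <- function() {
      eta <- stats::rnorm(p, 0, sqrt(truth$omega2))
      if (alpha_j > 0L) {
        a <- truth$tvp[alpha_j] * exp(eta[alpha_j])
        tries <- 0L
        while ((a < 0 || a > 1) && tries < 1000L) {
          eta[alpha_j] <- stats::rnorm(1, 0, sqrt(truth$omega2[alpha_j]))
          a <- truth$tvp[alpha_j] * exp(eta[alpha_j])
          tries <- tries + 1L
        }
        if (a < 0 || a > 1) {
          stop("could not draw alpha inside [0, 1] after 1000 attempts",
               call. = FALSE)
        }
      }
      eta
    }
    sched <- design$schedule
    etas <- matrix(0, M, p, dimnames = list(ids, model$param_names))
    rows <- vector("list", M)
    for (m in seq_len(M)) {
      # a patient whose sampled curve is non-positive at a sampled time
      # (possible in the far tails of the rate random effects) is redrawn
      for (attempt in seq_len(1000L)) {
        eta <- draw_eta()
        P <- truth$tvp * exp(eta)
        t_h <- numeric(nrow(sched))
        for (k in seq_len(nrow(sched))) {
          tk <- stats::rnorm(1, sched$mean_h[k], sched$sd_h[k])
          while (tk <= 0.1) {
            tk <- stats::rnorm(1, sched$mean_h[k], sched$sd_h[k])
          }
          t_h[k] <- tk
        }
        f <- soe_eval(model, P, t_h * 60)
        if (all(f > 0)) break
        if (attempt == 1000L) {
          stop("could not draw a positive time-activity curve", call. = FALSE)
        }
      }
      etas[m, ] <- eta
      y <- f * exp(stats::rnorm(length(f), 0, sqrt(truth$sigma2)))
      rows[[m]] <- data.frame(patient_id = ids[m], time_min = t_h * 60,
                              activity_pct = y)
    }
    params <- sweep(exp(etas), 2, truth$tvp, `*`)
    d <- do.call(rbind, rows)
    data <- biokinetics(d$patient_id, time_min = d$time_min,
                        activity_pct = d$activity_pct)
    tias <- vapply(seq_len(M), function(m) soe_tia(model, params[m, ]),
                   numeric(1))
    names(tias) <- ids
    list(data = data, params = params, etas = etas, true_tias = tias,
         design = design, truth = truth, seed = seed)
  })
}

#' True TIA of a simulated patient
#'
#' Closed-form TIA of the patient's true (simulated) parameters; for the
#' default `f4d` truth this is the patient's individual `A1`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param patient_id one of the simulated patient ids.
#' @return TIA in %.min.
#' @export
true_tia <- function(cohort, patient_id) {
  if (!patient_id %in% rownames(cohort$params)) {
    stop("unknown patient: ", patient_id, call. = FALSE)
  }
  unname(cohort$true_tias[patient_id])
}
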