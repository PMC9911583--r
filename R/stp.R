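#' Numerically integrated time-integrated activity
#'
#' Adaptive quadrature of a model curve over `[0, t_end]` minutes (default
#' 100,000 min).  The integration interval is split near the origin because
#' the fast blood-circulation term creates a boundary layer a few minutes
#' wide.
#'
#' @param model model id or [soe_model()].
#' @param params named parameter vector.
#' @param t_end upper integration limit in minutes.
#' @param constants a [decay_constants()] object.
#' @param rel_tol relative quadrature tolerance.
#' @return TIA in %.min.
#' @export
tia_numeric <- function(model, params, t_end = 1e5,
                        constants = decay_constants(), rel_tol = 1e-6) {
  stopifnot(t_end > 0)
  model <- soe_model(model)
  tr <- soe_terms(model, params, constants)
  if (all(tr$coef == 0)) return(0)
  f <- function(t) drop(exp(-outer(t, tr$rate)) %*% tr$coef)
  cuts <- unique(c(0, pmin(c(30, 2000), t_end),
                   10^seq(5, ceiling(log10(max(t_end, 1e5))), by = 1),
                   t_end))
  cuts <- cuts[cuts <= t_end]
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    q <- stats::integrate(f, cuts[i], cuts[i + 1L], rel.tol = rel_tol,
                          subdivisions = 500L)
    if (q$message != "OK") stop("quadrature failed: ", q$message,
                                call. = FALSE)
    total <- total + q$value
  }
  total
}

#' All-time-point reference TIAs
#'
#' Integrates each patient's empirical-Bayes individual curve from a
#' population fit on the complete dataset.
#'
#' @param fit a converged [fit_population()] result on all data.
#' @param t_end upper integration limit in minutes.
#' @return Data frame with columns `patient_id`, `tia`, `method` ("ATP"),
#'   `model`, `stp_time_label` (NA).
#' @export
atp_reference_tias <- function(fit, t_end = 1e5) {
  stopifnot(inherits(fit, "pop_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  tia <- vapply(fit$patients, function(m) {
    tia_numeric(fit$model, individual_params(fit, m), t_end = t_end,
                constants = fit$constants)
  }, numeric(1))
  data.frame(patient_id = fit$patients, tia = unname(tia), method = "ATP",
             model = fit$model$id, stp_time_label = NA_character_,
             row.names = NULL)
}

# Nominal imaging schedule (hours): means and SDs of the five sessions.
.default_schedule <- function() {
  data.frame(label = c("T1", "T2", "T3", "T4", "T5"),
             mean_h = c(2.9, 4.6, 22.8, 46.7, 70.9),
             sd_h = c(0.6, 0.4, 1.6, 1.7, 1.0))
}

.pick_stp_obs <- function(data, target, time_label, tol_h = 3) {
  sched <- .default_schedule()
  nominal <- sched$mean_h[sched$label == time_label] * 60
  if (length(nominal) != 1L) {
    stop("unknown STP time label: ", time_label, call. = FALSE)
  }
  obs <- data[data$patient_id == target, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations for patient ", target,
                            call. = FALSE)
  i <- which.min(abs(obs$time_min - nominal))
  if (abs(obs$time_min[i] - nominal) > tol_h * 60) {
    warning("selected observation of ", target, " is ",
            round(abs(obs$time_min[i] - nominal) / 60, 1),
            " h from the nominal ", time_label, " time", call. = FALSE)
  }
  obs[i, , drop = FALSE]
}

#' Single-time-point TIA of one patient
#'
#' Computes the STP TIA of a target patient from one measurement by fitting
#' the NLME model jointly to this single observation and the complete data
#' of all other patients, then integrating the target's empirical-Bayes
#' curve.  Two modes are available: `"refit"` re-estimates all population
#' parameters on the augmented dataset (the default), `"frozen"` keeps the
#' population parameters of `atp_fit` and only computes the target's MAP
#' random effects.
#'
#' @param data the full [biokinetics()] dataset (all patients).
#' @param target patient id whose TIA is computed from a single point.
#' @param model model id or [soe_model()].
#' @param time_label which imaging session supplies the single observation,
#'   `"T3"` or `"T4"` (nearest observation within 3 h; a warning is given
#'   outside the tolerance).
#' @param mode `"refit"` or `"frozen"`.
#' @param control a [fit_control()] list for the refit.
#' @param atp_fit optional all-data fit of the same model used to warm-start
#'   the refit (required for `mode = "frozen"`).
#' @param all_points if `TRUE`, the target keeps all its observations
#'   (consistency check against the ATP TIA).
#' @param t_end upper integration limit in minutes.
#' @param constants a [decay_constants()] object.
#' @return One-row data frame like [atp_reference_tias()] with
#'   `method = "STP"`.
#' @export
stp_tia <- function(data, target, model, time_label = c("T4", "T3"),
                    mode = c("refit", "frozen"), control = fit_control(),
                    atp_fit = NULL, all_points = FALSE, t_end = 1e5,
                    constants = decay_constants()) {
  model <- soe_model(model)
  mode <- match.arg(mode)
  time_label <- match.arg(time_label)
  others <- data[data$patient_id != target, , drop = FALSE]
  if (nrow(others) == 0L || length(unique(others$patient_id)) < 1L) {
    stop("no population data besides the target patient", call. = FALSE)
  }
  target_obs <- if (all_points) {
    data[data$patient_id == target, , drop = FALSE]
  } else {
    .pick_stp_obs(data, target, time_label)
  }
  if (nrow(target_obs) == 0L) {
    stop("target patient has no usable observation", call. = FALSE)
  }
  if (mode == "frozen") {
    if (is.null(atp_fit)) stop("frozen mode needs `atp_fit`", call. = FALSE)
    eb <- empirical_bayes(atp_fit, target_obs)
    pars <- eb$params
  } else {
    aug <- rbind(as.data.frame(others), as.data.frame(target_obs))
    aug <- biokinetics(aug$patient_id, time_min = aug$time_min,
                       activity_pct = aug$activity_pct)
    ctl <- control
    ctl$compute_cov <- FALSE
    if (!is.null(atp_fit) && isTRUE(atp_fit$converged) &&
        atp_fit$model$id == model$id && is.null(ctl$init)) {
      ctl$init <- list(tvp = atp_fit$tvp, omega2 = atp_fit$omega2,
                       sigma2 = atp_fit$sigma2)
    }
    refit <- fit_population(aug, model, control = ctl, constants = constants)
    if (!isTRUE(refit$converged)) {
      stop("STP refit did not converge for target ", target, call. = FALSE)
    }
    pars <- individual_params(refit, target)
  }
  data.frame(patient_id = target,
             tia = tia_numeric(model, pars, t_end = t_end,
                               constants = constants),
             method = "STP", model = model$id,
             stp_time_label = if (all_points) NA_character_ else time_label,
             row.names = NULL)
}

#' STP TIAs for every patient of a cohort
#'
#' Applies [stp_tia()] in turn to each patient (each acting once as the
#' "new" patient contributing a single measurement).
#'
#' @inheritParams stp_tia
#' @return Data frame with one STP row per patient.
#' @export
stp_cohort_tias <- function(data, model, time_label = c("T4", "T3"),
                            mode = c("refit", "frozen"),
                            control = fit_control(), atp_fit = NULL,
                            t_end = 1e5, constants = decay_constants()) {
  time_label <- match.arg(time_label)
  mode <- match.arg(mode)
  out <- lapply(patients(data), function(m) {
    stp_tia(data, m, model, time_label = time_label, mode = mode,
            control = control, atp_fit = atp_fit, t_end = t_end,
            constants = constants)
  })
  do.call(rbind, out)
}

#' Relative deviation from a reference TIA
#'
#' @param tia computed TIA(s).
#' @param reference_tia reference TIA(s); must be non-zero.
#' @return `(tia - reference_tia) / reference_tia`.
#' @export
relative_deviation <- function(tia, reference_tia) {
  if (any(reference_tia == 0)) stop("zero reference TIA", call. = FALSE)
  (tia - reference_tia) / reference_tia
}

#' RD accuracy summary (mean, SD, RMSE)
#'
#' Summarises per-patient relative deviations as
#' `RMSE = sqrt(MeanRD^2 + SDRD^2)`.  With the default population-SD
#' convention (divide by n) the RMSE equals the literal root-mean-square of
#' the deviations; the sample-SD convention (n-1) is available as an
#' option.
#'
#' @param rds non-empty numeric vector of relative deviations.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return An object of class `accuracy_report`: list with `rds`,
#'   `mean_rd`, `sd_rd`, `rmse`, `sd_type`.
#' @examples
#' rd_rmse(c(0.1, -0.1))$rmse # 0.1
#' @export
rd_rmse <- function(rds, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(rds) == 0L) stop("empty RD vector", call. = FALSE)
  m <- mean(rds)
  s <- if (sd_type == "population") {
    sqrt(mean((rds - m)^2))
  } else {
    stats::sd(rds)
  }
  if (length(rds) == 1L && sd_type == "sample") s <- 0
  structure(list(rds = rds, mean_rd = m, sd_rd = s,
                 rmse = sqrt(s^2 + m^2), sd_type = sd_type),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "TIA accuracy over %d patients: mean RD %.2f%%, SD %.2f%%, RMSE %.2f%%\n",
    length(x$rds), 100 * x$mean_rd, 100 * x$sd_rd, 100 * x$rmse))
  invisible(x)
}
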