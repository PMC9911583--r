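#' Configuration of an end-to-end analysis run
#'
#' @param models candidate model ids (default: all eleven).
#' @param seed top-level seed; every random step of the run derives from it.
#' @param multistart optimisation starts per fit.
#' @param cv_threshold goodness-of-fit gate on the fixed-effect CV (%).
#' @param jackknife_threshold full-data weight above which a model enters
#'   the jackknife candidate set.
#' @param stp_time_label imaging session used for the single measurement
#'   ("T3" or "T4"); both are computed when `stp_both = TRUE`.
#' @param stp_both compute STP accuracy at both T3 and T4.
#' @param stp_mode `"refit"` (joint re-estimation) or `"frozen"`.
#' @param comparison_model additional function whose STP accuracy is
#'   compared to the selected model's (default the bi-exponential `f3d`).
#' @param t_end TIA integration limit in minutes.
#' @param sd_type RD summary convention, `"population"` or `"sample"`.
#' @param half_life_days physical half-life of the nuclide in days.
#' @param run_jackknife whether to run the jackknife stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(models = soe_model_ids(), seed = 1L, multistart = 10L,
                       cv_threshold = 50, jackknife_threshold = 0.01,
                       stp_time_label = "T4", stp_both = FALSE,
                       stp_mode = "refit", comparison_model = "f3d",
                       t_end = 1e5, sd_type = "population",
                       half_life_days = 2.8047, run_jackknife = TRUE) {
  stopifnot(cv_threshold > 0, cv_threshold <= 100,
            jackknife_threshold > 0, jackknife_threshold <= 1,
            t_end > 0, stp_time_label %in% c("T3", "T4"))
  structure(list(models = models, seed = as.integer(seed),
                 multistart = as.integer(multistart),
                 cv_threshold = cv_threshold,
                 jackknife_threshold = jackknife_threshold,
                 stp_time_label = stp_time_label, stp_both = stp_both,
                 stp_mode = stp_mode, comparison_model = comparison_model,
                 t_end = t_end, sd_type = sd_type,
                 half_life_days = half_life_days,
                 run_jackknife = run_jackknife),
            class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stp_accuracy <- function(data, model, label, config, control, atp_fit,
                          reference, constants) {
  tab <- stp_cohort_tias(data, model, time_label = label,
                         mode = config$stp_mode, control = control,
                         atp_fit = atp_fit, t_end = config$t_end,
                         constants = constants)
  ref <- reference$tia[match(tab$patient_id, reference$patient_id)]
  rds <- relative_deviation(tab$tia, ref)
  list(tias = tab, accuracy = rd_rmse(rds, sd_type = config$sd_type))
}

#' Run the full analysis pipeline
#'
#' Fits all candidate models, applies the goodness-of-fit gate, ranks the
#' survivors by Akaike weight, assesses stability with the
#' leave-one-patient-out jackknife, computes all-time-point reference TIAs
#' with the selected model, performs STP dosimetry for every patient with
#' the selected model and the comparison function, and summarises the
#' relative deviations.  Optionally writes the selection table, the TIA
#' table, the accuracy report and a run log to `out_dir`.
#'
#' @param data a [biokinetics()] dataset (e.g. from [read_biokinetics()] or
#'   [simulate_cohort()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return A list with `selection`, `jackknife`, `atp`, `stp` (per-label,
#'   per-model TIA tables and accuracy reports), `best_model` and `log`.
#' @export
run_pipeline <- function(data, config = run_config(), out_dir = NULL) {
  constants <- decay_constants(config$half_life_days)
  control <- fit_control(multistart = config$multistart, seed = config$seed)
  message("stage fit/select: fitting ", length(config$models), " models")
  selection <- select_models(data, config$models, control = control,
                             cv_threshold = config$cv_threshold,
                             constants = constants)
  best <- best_fit(selection)
  message("stage select: best model ", best$model$id)

  jack <- NULL
  if (isTRUE(config$run_jackknife)) {
    message("stage jackknife")
    jack <- jackknife_weights(data, selection,
                              weight_threshold = config$jackknife_threshold,
                              control = control, constants = constants)
  }

  message("stage atp: reference TIAs")
  atp <- atp_reference_tias(best, t_end = config$t_end)

  labels <- if (isTRUE(config$stp_both)) c("T3", "T4") else
    config$stp_time_label
  stp <- list()
  for (lab in labels) {
    message("stage stp: ", lab)
    stp[[lab]] <- list(
      selected = .stp_accuracy(data, best$model$id, lab, config, control,
                               best, atp, constants),
      comparison = if (!is.null(config$comparison_model) &&
                       config$comparison_model != best$model$id) {
        cmp_fit <- attr(selection, "fits")[[config$comparison_model]]
        .stp_accuracy(data, config$comparison_model, lab, config, control,
                      cmp_fit, atp, constants)
      })
  }

  fits <- attr(selection, "fits")
  log <- list(seed = config$seed, config_hash = .config_hash(config),
              n_obs = nrow(data), n_patients = length(patients(data)),
              convergence = as.list(vapply(fits, function(f)
                isTRUE(f$converged), logical(1))),
              best_model = best$model$id)

  out <- list(selection = selection, jackknife = jack, atp = atp, stp = stp,
              best_model = best$model$id, log = log)
  if (!is.null(out_dir)) .write_reports(out, config, out_dir)
  out
}

.write_reports <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(out$selection),
                   file.path(out_dir, "selection.csv"), row.names = FALSE)
  tias <- out$atp
  acc <- list()
  for (lab in names(out$stp)) {
    for (kind in names(out$stp[[lab]])) {
      block <- out$stp[[lab]][[kind]]
      if (is.null(block)) next
      tias <- rbind(tias, block$tias)
      a <- block$accuracy
      acc[[paste(lab, block$tias$model[1], sep = "_")]] <-
        list(mean_rd = a$mean_rd, sd_rd = a$sd_rd, rmse = a$rmse,
             sd_type = a$sd_type, rds = a$rds)
    }
  }
  utils::write.csv(tias, file.path(out_dir, "tia.csv"), row.names = FALSE)
  jsonlite::write_json(acc, file.path(out_dir, "accuracy.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
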