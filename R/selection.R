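#' Number of NLME parameters of a model
#'
#' Each adjustable curve parameter contributes a fixed effect and a
#' random-effect variance, plus one residual variance for the error model:
#' `K = 2 * n_params + 1` (7, 9 and 11 for the 3-, 4- and 5-parameter
#' families).
#'
#' @param model model id or [soe_model()].
#' @return Integer K.
#' @export
parameter_count <- function(model) {
  model <- soe_model(model)
  2L * model$n_params + 1L
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = OFV + 2K + 2K(K+1)/(N-K-1)` with `OFV = -2 log` maximised
#' (marginal) likelihood.
#'
#' @param ofv objective value (-2 log likelihood) at the optimum.
#' @param K number of estimated parameters.
#' @param N number of observations; must exceed `K + 1`.
#' @return AICc value.
#' @examples
#' aicc(0, K = 9, N = 40) # 24
#' @export
aicc <- function(ofv, K, N) {
  if (any(N <= K + 1)) {
    stop("AICc correction undefined: need N > K + 1", call. = FALSE)
  }
  ofv + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

#' Akaike weights of a candidate set
#'
#' Weights `w_j = exp(-Delta_j/2) / sum_i exp(-Delta_i/2)` with
#' `Delta_j = AICc_j - min(AICc)`; the minimum is subtracted before
#' exponentiation for numerical safety.  Weights are positive and sum to 1,
#' and are invariant under adding a constant to all AICc values.
#'
#' @param aiccs non-empty numeric vector of finite AICc values.
#' @return Numeric vector of weights.
#' @examples
#' akaike_weights(c(0, 2 * log(3))) # 0.75, 0.25
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0L) stop("empty candidate set", call. = FALSE)
  if (any(!is.finite(aiccs))) stop("non-finite AICc value", call. = FALSE)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Goodness-of-fit gate on fixed-effect precision
#'
#' A fitted model passes when it converged and every fixed effect is
#' estimated with a coefficient of variation at or below the threshold
#' (default 50%).  Failing models are excluded from the Akaike-weight
#' computation and from downstream TIA accuracy metrics.
#'
#' @param fits list of [fit_population()] results.
#' @param cv_threshold maximum tolerated CV in percent.
#' @return Data frame with columns `model`, `converged`, `max_cv_percent`,
#'   `gof_pass`.
#' @export
goodness_of_fit_gate <- function(fits, cv_threshold = 50) {
  rows <- lapply(fits, function(f) {
    max_cv <- if (isTRUE(f$converged) && !is.null(f$cv_percent) &&
                  all(is.finite(f$cv_percent))) max(f$cv_percent) else Inf
    data.frame(model = f$model$id, converged = isTRUE(f$converged),
               max_cv_percent = max_cv,
               gof_pass = isTRUE(f$converged) && max_cv <= cv_threshold)
  })
  do.call(rbind, rows)
}

# (f4b, f4c) and (f4d, f4e) are reparameterisations of the same curve
# (alpha <-> 1 - alpha), so the better-converged member of each pair supplies
# an additional warm start for the other: a cheap guard against one member
# stopping in a local optimum the other escaped.
.polish_dual_pairs <- function(fits, data, control, constants) {
  pairs <- list(c("f4b", "f4c"), c("f4d", "f4e"))
  for (pr in pairs) {
    if (!all(pr %in% names(fits))) next
    f1 <- fits[[pr[1]]]
    f2 <- fits[[pr[2]]]
    if (!isTRUE(f1$converged) && !isTRUE(f2$converged)) next
    better <- if (!isTRUE(f2$converged) || (isTRUE(f1$converged) &&
                                            f1$ofv <= f2$ofv)) 1L else 2L
    worse <- 3L - better
    src <- fits[[pr[better]]]
    dst <- fits[[pr[worse]]]
    if (isTRUE(dst$converged) && dst$ofv - src$ofv < 1e-4) next
    tvp <- src$tvp
    tvp[["alpha"]] <- 1 - tvp[["alpha"]]
    ctl <- control
    ctl$init <- list(tvp = tvp, omega2 = unname(src$omega2),
                     sigma2 = src$sigma2)
    refit <- fit_population(data, pr[worse], control = ctl,
                            constants = constants)
    if (isTRUE(refit$converged) &&
        (!isTRUE(dst$converged) || refit$ofv < dst$ofv)) {
      fits[[pr[worse]]] <- refit
    }
  }
  fits
}

#' Fit and rank a set of candidate models
#'
#' Fits every candidate with [fit_population()], applies the
#' goodness-of-fit gate, computes AICc and Akaike weights over the
#' surviving models, and sorts by weight (ties broken by smaller `K`, then
#' by model id).
#'
#' @param data a [biokinetics()] dataset.
#' @param models character vector of model ids (default: all eleven).
#' @param control a [fit_control()] list applied to every fit.
#' @param cv_threshold goodness-of-fit CV gate in percent.
#' @param constants a [decay_constants()] object.
#' @return An object of class `selection_report`: a data frame with one row
#'   per model (`model`, `K`, `ofv`, `aicc`, `delta`, `weight`,
#'   `max_cv_percent`, `gof_pass`, `converged`) carrying the fit list in
#'   attribute `"fits"`.
#' @export
select_models <- function(data, models = soe_model_ids(),
                          control = fit_control(), cv_threshold = 50,
                          constants = decay_constants()) {
  stopifnot(length(models) >= 1L)
  fits <- lapply(models, function(id) {
    fit_population(data, id, control = control, constants = constants)
  })
  names(fits) <- models
  fits <- .polish_dual_pairs(fits, data, control, constants)
  gate <- goodness_of_fit_gate(fits, cv_threshold)
  N <- nrow(data)
  K <- vapply(models, parameter_count, integer(1))
  ofv <- vapply(fits, function(f) f$ofv, numeric(1))
  aiccs <- ifelse(is.finite(ofv), aicc(ofv, K, N), Inf)
  tab <- data.frame(model = models, K = K, ofv = ofv, aicc = aiccs,
                    delta = NA_real_, weight = NA_real_,
                    max_cv_percent = gate$max_cv_percent,
                    gof_pass = gate$gof_pass, converged = gate$converged,
                    row.names = NULL)
  surv <- which(tab$gof_pass & is.finite(tab$aicc))
  if (length(surv) == 0L) {
    stop("no model passed the goodness-of-fit gate", call. = FALSE)
  }
  tab$delta[surv] <- tab$aicc[surv] - min(tab$aicc[surv])
  tab$weight[surv] <- akaike_weights(tab$aicc[surv])
  o <- order(-ifelse(is.na(tab$weight), -Inf, tab$weight), tab$K, tab$model)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits, N = N, cv_threshold = cv_threshold,
            class = c("selection_report", "data.frame"))
}

#' Best model of a selection report
#' @param report a [select_models()] result.
#' @return The [fit_population()] result of the top-ranked model.
#' @export
best_fit <- function(report) {
  attr(report, "fits")[[report$model[1]]]
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model selection over", nrow(x), "candidate functions (N =",
      attr(x, "N"), "observations)\n")
  tab <- data.frame(model = x$model, K = x$K,
                    `weight %` = ifelse(is.na(x$weight), "-",
                                        sprintf("%.2f", 100 * x$weight)),
                    `max CV %` = ifelse(is.finite(x$max_cv_percent),
                                        sprintf("%.1f", x$max_cv_percent),
                                        "-"),
                    gof = ifelse(x$gof_pass, "pass", "fail"),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Leave-one-patient-out jackknife of the Akaike weights
#'
#' Refits the candidate models once per left-out patient and recomputes the
#' Akaike weights on each reduced cohort, giving a stability summary of the
#' full-data ranking.  By default the candidates are the models whose
#' full-data weight exceeds 1%.
#'
#' @param data a [biokinetics()] dataset with at least 3 patients.
#' @param report a [select_models()] result on the full data.
#' @param candidates model ids to include; default: full-data weight >
#'   `weight_threshold`.
#' @param weight_threshold candidate inclusion threshold on the full-data
#'   weight (default 0.01).
#' @param control a [fit_control()] list for the fold refits (fold fits are
#'   warm-started from the full-data estimates).
#' @param constants a [decay_constants()] object.
#' @return An object of class `jackknife_summary`: list with `folds`
#'   (patients x models weight matrix) and `summary` (per-model mean, sd,
#'   median, min, max of the weights in %).
#' @export
jackknife_weights <- function(data, report, candidates = NULL,
                              weight_threshold = 0.01,
                              control = fit_control(),
                              constants = decay_constants()) {
  ids <- patients(data)
  if (length(ids) < 3L) stop("jackknife requires >= 3 patients", call. = FALSE)
  if (is.null(candidates)) {
    candidates <- report$model[!is.na(report$weight) &
                                 report$weight > weight_threshold]
  }
  if (length(candidates) == 0L) stop("no candidate models", call. = FALSE)
  fits <- attr(report, "fits")
  K <- vapply(candidates, parameter_count, integer(1))
  folds <- matrix(NA_real_, length(ids), length(candidates),
                  dimnames = list(ids, candidates))
  for (m in ids) {
    sub <- data[data$patient_id != m, , drop = FALSE]
    class(sub) <- class(data)
    ofv <- rep(NA_real_, length(candidates))
    for (k in seq_along(candidates)) {
      id <- candidates[k]
      ctl <- control
      full <- fits[[id]]
      if (!is.null(full) && isTRUE(full$converged)) {
        ctl$init <- list(tvp = full$tvp, omega2 = full$omega2,
                         sigma2 = full$sigma2)
      }
      ctl$compute_cov <- FALSE
      f <- fit_population(sub, id, control = ctl, constants = constants)
      if (isTRUE(f$converged)) ofv[k] <- f$ofv
    }
    if (any(is.na(ofv))) {
      warning("jackknife fold without patient ", m,
              " dropped: fit failure", call. = FALSE)
      next
    }
    folds[m, ] <- akaike_weights(aicc(ofv, K, nrow(sub)))
  }
  used <- stats::complete.cases(folds)
  s <- apply(folds[used, , drop = FALSE] * 100, 2, function(w) {
    c(mean = mean(w), sd = stats::sd(w), median = stats::median(w),
      min = min(w), max = max(w))
  })
  structure(list(folds = folds, summary = t(s), n_folds = sum(used)),
            class = "jackknife_summary")
}

#' @export
print.jackknife_summary <- function(x, ...) {
  cat("Leave-one-patient-out jackknife of Akaike weights (",
      x$n_folds, " folds)\n", sep = "")
  s <- x$summary
  for (id in rownames(s)) {
    cat(sprintf("  %-4s %2.0f (%.0f); %2.0f [%.0f, %.0f]\n", id,
                s[id, "mean"], s[id, "sd"], s[id, "median"],
                s[id, "min"], s[id, "max"]))
  }
  cat("  (mean (SD); median [min, max] of weights in %)\n")
  invisible(x)
}
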