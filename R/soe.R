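#' @useDynLib msnlme, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Registry of the eleven sum-of-exponential parameterisations.
# code must match the switch in src/laplace.cpp.
# ordered: lambda1 <= lambda2 (<= lambda3) imposed to break the exchange
# symmetry of otherwise interchangeable decay rates.
# tia: closed-form time-integral in terms of the parameters, as a label.
.soe_registry <- list(
  f3a = list(code = 1L, params = c("A1", "lambda1", "lambda2"),
             ordered = TRUE,  alpha = NA_character_, tia = "A1*(1/(l1+lp)-1/(l2+lp))"),
  f3b = list(code = 2L, params = c("A1", "lambda1", "lambda2"),
             ordered = TRUE,  alpha = NA_character_, tia = "1/A1"),
  f3c = list(code = 3L, params = c("A1", "lambda1", "lambda2"),
             ordered = TRUE,  alpha = NA_character_, tia = "A1"),
  f3d = list(code = 4L, params = c("A1", "lambda1", "lambda2"),
             ordered = TRUE,  alpha = NA_character_, tia = "1/A1"),
  f4a = list(code = 5L, params = c("A1", "A2", "lambda1", "lambda2"),
             ordered = FALSE, alpha = NA_character_, tia = "sum(coef/rate)"),
  f4b = list(code = 6L, params = c("A1", "alpha", "lambda1", "lambda2"),
             ordered = FALSE, alpha = "alpha", tia = "sum(coef/rate)"),
  f4c = list(code = 7L, params = c("A1", "alpha", "lambda1", "lambda2"),
             ordered = FALSE, alpha = "alpha", tia = "sum(coef/rate)"),
  f4d = list(code = 8L, params = c("A1", "alpha", "lambda1", "lambda2"),
             ordered = FALSE, alpha = "alpha", tia = "A1"),
  f4e = list(code = 9L, params = c("A1", "alpha", "lambda1", "lambda2"),
             ordered = FALSE, alpha = "alpha", tia = "A1"),
  f5a = list(code = 10L, params = c("A1", "A2", "lambda1", "lambda2", "lambda3"),
             ordered = TRUE,  alpha = NA_character_, tia = "sum(coef/rate)"),
  f5b = list(code = 11L, params = c("A1", "A2", "A3", "lambda1", "lambda2"),
             ordered = FALSE, alpha = NA_character_, tia = "sum(coef/rate)")
)

#' Identifiers of the available sum-of-exponential models
#'
#' @return Character vector of the eleven model ids, `"f3a"` to `"f5b"`.
#' @export
soe_model_ids <- function() names(.soe_registry)

#' Sum-of-exponential model descriptor
#'
#' Looks up one of the eleven mono-, bi-, and tri-exponential
#' parameterisations used to fit organ time-activity curves.  All models obey
#' `f(0) = 0`; the four- and five-parameter forms include a fixed fast uptake
#' term with a one-minute half-life representing blood circulation.
#'
#' @param id model identifier, e.g. `"f4d"`, or an existing `soe_model`.
#' @return An object of class `soe_model` with elements `id`, `code`,
#'   `param_names`, `n_params`, `ordered` (whether a `lambda1 <= lambda2`
#'   ordering constraint applies) and `alpha_param`.
#' @examples
#' soe_model("f4d")
#' @export
soe_model <- function(id) {
  if (inherits(id, "soe_model")) return(id)
  if (!is.character(id) || length(id) != 1L || !id %in% names(.soe_registry)) {
    stop("unknown SOE model id: ", paste(format(id), collapse = ", "),
         " (use one of ", paste(names(.soe_registry), collapse = ", "), ")",
         call. = FALSE)
  }
  r <- .soe_registry[[id]]
  structure(
    list(id = id, code = r$code, param_names = r$params,
         n_params = length(r$params), ordered = r$ordered,
         alpha_param = r$alpha, tia_form = r$tia),
    class = "soe_model"
  )
}

#' @export
print.soe_model <- function(x, ...) {
  cat("Sum-of-exponentials model ", x$id, " (", x$n_params,
      " adjustable parameters)\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (x$ordered) cat("  constraint: lambda rates ordered increasingly\n")
  invisible(x)
}

.soe_param_vector <- function(model, params) {
  model <- soe_model(model)
  params <- unlist(params)
  if (is.null(names(params)) || all(names(params) == "")) {
    if (length(params) != model$n_params) {
      stop("model ", model$id, " needs ", model$n_params, " parameters",
           call. = FALSE)
    }
    names(params) <- model$param_names
  }
  missing <- setdiff(model$param_names, names(params))
  if (length(missing)) {
    stop("missing parameters for ", model$id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params[model$param_names]
}

#' Validate a parameter set against the model constraints
#'
#' Checks the parameter bounds of a sum-of-exponential model: prefactors
#' `A_j >= 0`, rates `lambda_j >= 0`, fractional contributions
#' `alpha` in `[0, 1]`, and the increasing ordering of exchangeable rates
#' where the parameterisation requires it.
#'
#' @param model model id or `soe_model`.
#' @param params named numeric vector (or list) of parameter values.
#' @return Character vector of violations; empty when the set is valid.
#' @examples
#' soe_validate("f4d", c(A1 = 129.36, alpha = 1.2, lambda1 = 1.5e-4, lambda2 = 8.8e-4))
#' @export
soe_validate <- function(model, params) {
  model <- soe_model(model)
  p <- .soe_param_vector(model, params)
  bad <- character(0)
  if (any(!is.finite(p))) bad <- c(bad, "non-finite parameter value")
  amp <- grep("^A", model$param_names, value = TRUE)
  if (any(p[amp] < 0, na.rm = TRUE)) {
    bad <- c(bad, paste0("prefactor(s) ",
                         paste(amp[p[amp] < 0], collapse = ", "), " < 0"))
  }
  lam <- grep("^lambda", model$param_names, value = TRUE)
  if (any(p[lam] < 0, na.rm = TRUE)) {
    bad <- c(bad, paste0("rate(s) ",
                         paste(lam[p[lam] < 0], collapse = ", "), " < 0"))
  }
  if (!is.na(model$alpha_param)) {
    a <- p[model$alpha_param]
    if (is.finite(a) && (a < 0 || a > 1)) {
      bad <- c(bad, "alpha outside [0, 1]")
    }
  }
  if (model$ordered && all(is.finite(p[lam]))) {
    if (any(diff(p[lam]) < 0)) {
      bad <- c(bad, "rate ordering violated (lambda1 <= lambda2 <= ... required)")
    }
  }
  bad
}

.soe_check <- function(model, params) {
  model <- soe_model(model)
  p <- .soe_param_vector(model, params)
  bad <- soe_validate(model, p)
  if (length(bad)) {
    stop("invalid parameters for ", model$id, ": ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  if (model$id %in% c("f3b", "f3c", "f3d") && p["lambda1"] == p["lambda2"]) {
    stop("degenerate parameters for ", model$id,
         ": lambda1 == lambda2 (division by zero)", call. = FALSE)
  }
  p
}

#' Exponential-term representation of a model
#'
#' Expands a parameterisation into `f(t) = sum_k coef_k exp(-rate_k t)` with
#' rates in 1/min (physical decay included where the model adds it).  The
#' coefficients sum exactly to zero, so `f(0) = 0` holds in floating point.
#'
#' @inheritParams soe_validate
#' @param constants a [decay_constants()] object.
#' @return List with numeric vectors `coef` and `rate`.
#' @export
soe_terms <- function(model, params, constants = decay_constants()) {
  model <- soe_model(model)
  p <- .soe_check(model, params)
  tr <- cpp_soe_terms(model$code, unname(p), constants$lambda_phys,
                      constants$lambda_bc)
  if (!tr$ok) {
    stop("degenerate parameters for ", model$id, call. = FALSE)
  }
  list(coef = as.numeric(tr$coef), rate = as.numeric(tr$rate))
}

#' Evaluate a sum-of-exponential time-activity function
#'
#' @inheritParams soe_terms
#' @param times times in minutes post injection (non-negative).
#' @return Activities in % of the administered activity, one per time.
#' @examples
#' soe_eval("f4d", c(A1 = 129.36, alpha = 0.31, lambda1 = 1.5e-4,
#'                   lambda2 = 8.8e-4), times = c(0, 60, 1440))
#' @export
soe_eval <- function(model, params, times, constants = decay_constants()) {
  if (any(times < 0)) stop("`times` must be >= 0 (minutes)", call. = FALSE)
  tr <- soe_terms(model, params, constants)
  out <- drop(exp(-outer(times, tr$rate)) %*% tr$coef)
  out[times == 0] <- 0 # exact: the coefficients sum to zero by construction
  out
}

#' Closed-form time-integrated activity of a model
#'
#' Term-by-term integration of `f` over `[0, Inf)` gives
#' `sum_k coef_k / rate_k` (in %.min).  For `f4d`, `f4e` and `f3c` this is
#' exactly `A1`; for `f3b` and `f3d` exactly `1/A1`.
#'
#' @inheritParams soe_terms
#' @return Time-integrated activity in %.min.
#' @examples
#' soe_tia("f4d", c(A1 = 129.36, alpha = 0.31, lambda1 = 1.5e-4,
#'                  lambda2 = 8.8e-4)) # exactly A1
#' @export
soe_tia <- function(model, params, constants = decay_constants()) {
  tr <- soe_terms(model, params, constants)
  if (all(tr$coef == 0)) return(0)
  if (any(tr$rate[tr$coef != 0] <= 0)) {
    stop("infinite time-integrated activity: a non-vanishing term has rate 0",
         call. = FALSE)
  }
  sum(tr$coef / tr$rate)
}
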