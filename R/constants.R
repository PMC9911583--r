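#' Decay constants used by the sum-of-exponential models
#'
#' The fit functions carry two fixed rate constants: the physical decay rate
#' of the radionuclide and a fast blood-circulation uptake rate with a
#' half-life of one minute.  The default physical half-life is that of
#' In-111 (2.8047 d), giving `lambda_phys = 1.72e-4 / min` to three
#' significant digits; it can be overridden for other nuclides.
#'
#' @param half_life_days physical half-life of the nuclide in days.
#' @return A list of class `decay_constants` with elements `lambda_phys` and
#'   `lambda_bc`, both in 1/min.
#' @examples
#' decay_constants()$lambda_phys # ~1.72e-4 /min for In-111
#' @export
decay_constants <- function(half_life_days = 2.8047) {
  stopifnot(is.numeric(half_life_days), length(half_life_days) == 1L,
            half_life_days > 0)
  structure(
    list(lambda_phys = log(2) / (half_life_days * 24 * 60),
         lambda_bc = log(2) / 1),
    class = "decay_constants"
  )
}

#' Convert a rate constant to a half-life in hours
#'
#' @param rate decay rate in 1/min; must be positive.
#' @return Half-life `ln(2)/rate` expressed in hours.
#' @examples
#' half_life_hours(1.5e-4) # ~77 h
#' half_life_hours(8.8e-4) # ~13.1 h
#' @export
half_life_hours <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be a positive finite rate in 1/min", call. = FALSE)
  }
  log(2) / rate / 60
}
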