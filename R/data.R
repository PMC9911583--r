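#' Biokinetic time-activity dataset
#'
#' Constructs the long-format container used throughout the package: one row
#' per measurement, with a patient label, the time post injection and the
#' measured activity as % of the administered activity.  Activities must be
#' strictly positive because fitting works on log-transformed observations.
#'
#' @param patient_id patient labels (coerced to character).
#' @param time_h times in hours post injection (exclusive with `time_min`).
#' @param activity_pct activities in % administered activity, all > 0.
#' @param time_min times in minutes post injection.
#' @return A `data.frame` of class `biokinetics` with columns `patient_id`,
#'   `time_min` and `activity_pct`, ordered by patient then time.
#' @examples
#' biokinetics(c("P1", "P1"), time_h = c(3, 24), activity_pct = c(2.1, 1.4))
#' @export
biokinetics <- function(patient_id, time_h = NULL, activity_pct,
                        time_min = NULL) {
  if (is.null(time_min) == is.null(time_h)) {
    stop("supply exactly one of `time_h` or `time_min`", call. = FALSE)
  }
  if (is.null(time_min)) time_min <- as.numeric(time_h) * 60
  d <- data.frame(patient_id = as.character(patient_id),
                  time_min = as.numeric(time_min),
                  activity_pct = as.numeric(activity_pct),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$time_min)) || any(d$time_min <= 0)) {
    stop("all measurement times must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(d$activity_pct)) || any(d$activity_pct <= 0)) {
    bad <- which(!is.finite(d$activity_pct) | d$activity_pct <= 0)
    stop("non-positive or non-finite activity in row(s) ",
         paste(bad, collapse = ", "),
         " (the log-scale error model requires activity > 0)", call. = FALSE)
  }
  key <- paste(d$patient_id, d$time_min)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, time) pairs in row(s) ",
         paste(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
               collapse = ", "), call. = FALSE)
  }
  d <- d[order(d$patient_id, d$time_min), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("biokinetics", "data.frame")
  d
}

#' @export
print.biokinetics <- function(x, ...) {
  cat("Biokinetic dataset: ", length(unique(x$patient_id)), " patients, ",
      nrow(x), " observations\n", sep = "")
  NextMethod()
}

#' Patients in a biokinetic dataset
#' @param data a [biokinetics()] dataset.
#' @return Character vector of unique patient ids in order of appearance.
#' @export
patients <- function(data) unique(data$patient_id)

#' Read a biokinetic CSV table
#'
#' Expects columns `patient_id`, `time_h` and `activity_pct` (header matching
#' is case-insensitive); times are converted from hours to the internal
#' minute scale on read.
#'
#' @param path path to a CSV file.
#' @return A [biokinetics()] dataset.
#' @export
read_biokinetics <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("patient_id", "time_h", "activity_pct")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  biokinetics(d$patient_id, time_h = d$time_h, activity_pct = d$activity_pct)
}

#' Write a biokinetic dataset as CSV
#'
#' Writes columns `patient_id`, `time_h`, `activity_pct`; the internal minute
#' scale is converted back to hours at full precision so a write/read
#' round-trip is the identity.
#'
#' @param data a [biokinetics()] dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biokinetics <- function(data, path) {
  out <- data.frame(patient_id = data$patient_id,
                    time_h = data$time_min / 60,
                    activity_pct = data$activity_pct)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.split_patients <- function(data) {
  split(data[, c("time_min", "activity_pct")], data$patient_id)[patients(data)]
}
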