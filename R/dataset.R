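# SubjectRecord / Dataset containers: the unit of fitting.

#' One animal's dose, weight, and time-stamped observations
#'
#' @param subject_id opaque label, unique within a dataset.
#' @param body_weight body weight, g.
#' @param dose [dose_event()].
#' @param times observation times, h; non-negative, strictly increasing.
#' @param conc observed concentrations, mg/L; strictly positive (the assay
#'   reports positive values; non-positive observations are rejected).
#' @param group optional group label.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, body_weight, dose, times, conc,
                           group = NA_character_) {
  stopifnot(length(subject_id) == 1L)
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop("body_weight must be a single positive number (g)", call. = FALSE)
  if (!inherits(dose, "dose_event")) stop("'dose' must be a dose_event",
                                          call. = FALSE)
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc))
    stop("times and conc must have equal length", call. = FALSE)
  if (length(times) == 0L) stop("subject '", subject_id,
                                "' has no observations", call. = FALSE)
  if (any(times < 0)) stop("subject '", subject_id,
                           "': observation times must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("subject '", subject_id,
         "': observation times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("subject '", subject_id,
         "': concentrations must be finite and > 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 body_weight = body_weight, dose = dose,
                 times = times, conc = conc,
                 group = as.character(group)),
            class = "subject_record")
}

#' Longitudinal concentration dataset
#'
#' @param subjects list of [subject_record()]s with unique ids; at least one
#'   subject must carry a post-dose (t > 0) observation.
#' @param study study label stored in the metadata.
#' @param units named list declaring units (defaults: concentration mg/L,
#'   weight g, time h).
#' @return An object of class `mi_dataset`.
#' @export
mi_dataset <- function(subjects, study = "unnamed",
                       units = list(concentration = "mg/L", weight = "g",
                                    time = "h")) {
  if (!is.list(subjects) || length(subjects) == 0L ||
      !all(vapply(subjects, inherits, logical(1), "subject_record")))
    stop("'subjects' must be a non-empty list of subject_record objects",
         call. = FALSE)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique: ",
                               paste(ids[duplicated(ids)], collapse = ", "),
                               call. = FALSE)
  if (!any(vapply(subjects, function(s) any(s$times > 0), logical(1))))
    stop("dataset must contain at least one post-dose observation",
         call. = FALSE)
  structure(list(subjects = subjects,
                 metadata = list(study = study, units = units)),
            class = "mi_dataset")
}

#' @export
print.mi_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) length(s$times), integer(1)))
  cat(sprintf("mi_dataset '%s': %d subjects, %d observations\n",
              x$metadata$study, length(x$subjects), n_obs))
  invisible(x)
}

# Flat observation table used by the likelihood and the reporters:
# one row per observation with that subject's dose amount attached.
#' @keywords internal
obs_table <- function(dataset) {
  stopifnot(inherits(dataset, "mi_dataset"))
  do.call(rbind, lapply(dataset$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               group = s$group,
               body_weight = s$body_weight,
               time = s$times, conc = s$conc,
               amount = s$dose$amount,
               stringsAsFactors = FALSE)
  }))
}

#' @keywords internal
n_observations <- function(dataset) {
  sum(vapply(dataset$subjects, function(s) length(s$times), integer(1)))
}
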