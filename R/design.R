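# Study designs: group -> sampling-schedule maps with body weights and a
# weight-based dose rule. The built-in design reproduces the published
# sparse three-group rat study.

#' Sparse-sampling study design
#'
#' @param groups list of groups, each a list with `label`, `times` (sampling
#'   times in h; must include 0, the pre-dose baseline sample; unique and
#'   sorted) and `n` (subject count >= 1).
#' @param weights either a numeric vector of body weights in g (one per
#'   subject, in group order) or a length-2 numeric range `c(min, max)` from
#'   which weights are drawn uniformly at simulation time.
#' @param dose_per_kg weight-based oral dose rule, g/kg (default 2).
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups, weights = c(300, 390), dose_per_kg = 2) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a non-empty list", call. = FALSE)
  for (g in groups) {
    if (!all(c("label", "times", "n") %in% names(g)))
      stop("each group needs 'label', 'times', 'n'", call. = FALSE)
    tms <- g$times
    if (!is.numeric(tms) || anyDuplicated(tms) || is.unsorted(tms) ||
        any(tms < 0))
      stop("group '", g$label,
           "': times must be unique, sorted and non-negative", call. = FALSE)
    if (!0 %in% tms)
      stop("group '", g$label,
           "': schedule must include time 0 (pre-dose baseline sample)",
           call. = FALSE)
    if (g$n < 1) stop("group '", g$label, "': subject count must be >= 1",
                      call. = FALSE)
  }
  n_total <- sum(vapply(groups, `[[`, numeric(1), "n"))
  fixed_weights <- length(weights) == n_total && n_total != 2
  if (!fixed_weights && length(weights) != 2L)
    stop("'weights' must be one weight per subject or a c(min, max) range",
         call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive (g)", call. = FALSE)
  if (!is.numeric(dose_per_kg) || dose_per_kg <= 0)
    stop("dose_per_kg must be > 0", call. = FALSE)
  structure(list(groups = groups, weights = weights,
                 fixed_weights = fixed_weights,
                 dose_per_kg = dose_per_kg),
            class = "study_design")
}

#' The published nine-rat study design
#'
#' The sparse three-group Wistar rat design: 3 rats per group, oral dose
#' 2 g/kg, group schedules (h) `{0, 0.25, 0.5, 1, 24}`,
#' `{0, 2, 4, 8, 12, 24}` and `{0, 1.5, 36, 48}`, and the nine recorded
#' body weights (g) bound to ids 1A-3A, 1B-3B, 1C-3C.
#'
#' @return A [study_design()] with fixed weights.
#' @export
rat_study_design <- function() {
  study_design(
    groups = list(
      list(label = "1", times = c(0, 0.25, 0.5, 1, 24), n = 3),
      list(label = "2", times = c(0, 2, 4, 8, 12, 24), n = 3),
      list(label = "3", times = c(0, 1.5, 36, 48), n = 3)),
    weights = c(328, 316, 302, 309, 317, 330, 391, 361, 359),
    dose_per_kg = 2)
}

# one row per subject: id, group label, schedule index, fixed weight (or NA)
#' @keywords internal
design_subjects <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  idx <- 0L
  for (gi in seq_along(design$groups)) {
    g <- design$groups[[gi]]
    for (si in seq_len(g$n)) {
      idx <- idx + 1L
      id <- paste0(si, LETTERS[gi])
      rows[[idx]] <- list(subject_id = id, group = g$label, group_index = gi,
                          weight = if (design$fixed_weights)
                            design$weights[idx] else NA_real_)
    }
  }
  rows
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d groups, %d subjects, dose %g g/kg\n",
              length(x$groups),
              sum(vapply(x$groups, `[[`, numeric(1), "n")), x$dose_per_kg))
  for (g in x$groups)
    cat(sprintf("  group %s (n=%d): %s h\n", g$label, g$n,
                paste(g$times, collapse = ", ")))
  invisible(x)
}
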