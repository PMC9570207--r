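# Domain types: structural parameters, dose events, secondary parameters.

#' Structural pharmacokinetic parameters
#'
#' Bundle of the four primary parameters of the one-compartment oral model
#' with endogenous baseline, plus the proportional residual error SD. The
#' endogenous input rate is never stored: at steady state it is fully
#' determined by `k_in = c0 * cl_f` (see [steady_state_kin()]).
#'
#' @param ka absorption rate constant, 1/h. Must be > 0.
#' @param cl_f apparent clearance CL/F, L/h. Must be > 0. Clearance and
#'   volume are apparent (confounded with oral bioavailability F).
#' @param v_f apparent central volume V/F, L. Must be > 0.
#' @param c0 endogenous steady-state concentration, mg/L. Must be >= 0.
#' @param sigma proportional residual error SD (dimensionless). Must be >= 0.
#'
#' @return An object of class `structural_params`: a named list with the
#'   five fields above.
#' @seealso [secondary_parameters()], [mi_concentration()]
#' @examples
#' structural_params(ka = 1.89, cl_f = 0.853, v_f = 5.1, c0 = 10, sigma = 0.243)
#' @export
structural_params <- function(ka, cl_f, v_f, c0, sigma = 0) {
  p <- list(ka = as.numeric(ka), cl_f = as.numeric(cl_f),
            v_f = as.numeric(v_f), c0 = as.numeric(c0),
            sigma = as.numeric(sigma))
  class(p) <- "structural_params"
  validate_structural_params(p)
  p
}

#' @keywords internal
validate_structural_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("ka", "cl_f", "v_f", "c0", "sigma")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a single finite number",
                            call. = FALSE)
  }
  if (p$ka <= 0)    stop("ka must be > 0", call. = FALSE)
  if (p$cl_f <= 0)  stop("cl_f must be > 0", call. = FALSE)
  if (p$v_f <= 0)   stop("v_f must be > 0", call. = FALSE)
  if (p$c0 < 0)     stop("c0 must be >= 0", call. = FALSE)
  if (p$sigma < 0)  stop("sigma must be >= 0", call. = FALSE)
  kel <- p$cl_f / p$v_f
  if (!is.finite(kel) || kel <= 0) stop("derived k_el must be finite and > 0",
                                        call. = FALSE)
  invisible(p)
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural PK parameters (one-compartment, oral, endogenous baseline)\n")
  cat(sprintf("  ka    = %g 1/h   (absorption rate constant)\n", x$ka))
  cat(sprintf("  CL/F  = %g L/h   (apparent clearance)\n", x$cl_f))
  cat(sprintf("  V/F   = %g L     (apparent central volume)\n", x$v_f))
  cat(sprintf("  C0    = %g mg/L  (endogenous baseline)\n", x$c0))
  cat(sprintf("  sigma = %g       (proportional residual SD)\n", x$sigma))
  cat(sprintf("  k_el  = %g 1/h   (derived, CL/F / V/F)\n", x$cl_f / x$v_f))
  invisible(x)
}

#' Single oral dose event
#'
#' A dose administered at time 0 (single oral gavage). The amount can be
#' given directly in mg, or derived from a weight-based rule
#' `amount = dose_per_kg * body_weight_kg * 1000`.
#'
#' @param amount administered amount, mg. If `NULL`, computed from
#'   `dose_per_kg` and `body_weight`.
#' @param time administration time, h (fixed at 0 for this design).
#' @param dose_per_kg nominal dose, g per kg body weight (the study used 2).
#' @param body_weight body weight in g (used only when `amount` is `NULL`).
#' @return An object of class `dose_event` with fields `amount`, `time`,
#'   `dose_per_kg`.
#' @examples
#' dose_event(dose_per_kg = 2, body_weight = 328)  # 656 mg
#' @export
dose_event <- function(amount = NULL, time = 0, dose_per_kg = NA_real_,
                       body_weight = NULL) {
  if (is.null(amount)) {
    if (!is.numeric(dose_per_kg) || !is.numeric(body_weight))
      stop("either 'amount' or both 'dose_per_kg' and 'body_weight' required",
           call. = FALSE)
    # g/kg * g body weight = mg (the g->kg and g->mg factors cancel)
    amount <- dose_per_kg * body_weight
  }
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) ||
      amount < 0)
    stop("dose amount must be a single finite number >= 0", call. = FALSE)
  if (!identical(as.numeric(time), 0))
    stop("only dosing at time 0 is supported (single oral gavage design)",
         call. = FALSE)
  structure(list(amount = as.numeric(amount), time = 0,
                 dose_per_kg = as.numeric(dose_per_kg)),
            class = "dose_event")
}

#' Allometric weight scaling of clearance and volume
#'
#' Optional covariate model scaling the apparent clearance by
#' `(WT/WT_ref)^0.75` and the apparent volume by `(WT/WT_ref)^1`. Disabled
#' by default everywhere; the primary analysis uses a single typical value
#' per parameter.
#'
#' @param params [structural_params()] typical values.
#' @param body_weight subject body weight, g.
#' @param ref_weight reference weight, g (e.g. the median study weight).
#' @return A `structural_params` object with scaled `cl_f` and `v_f`.
#' @export
allometric_scale <- function(params, body_weight, ref_weight) {
  validate_structural_params(params)
  stopifnot(is.numeric(body_weight), body_weight > 0,
            is.numeric(ref_weight), ref_weight > 0)
  w <- body_weight / ref_weight
  structural_params(ka = params$ka,
                    cl_f = params$cl_f * w^0.75,
                    v_f = params$v_f * w,
                    c0 = params$c0, sigma = params$sigma)
}
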