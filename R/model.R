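# Structural model: closed-form and numerical concentration-time curves for
# a single oral dose superimposed on an endogenous steady state.
#
# Model: first-order absorption from a depot (amount A), one central
# compartment (amount X) with linear elimination and a zero-order endogenous
# input k_in that sustains the pre-dose steady state C0:
#   dA/dt = -ka * A                        A(0) = dose
#   dX/dt = k_in - (CL/F / V/F) * X + ka*A X(0) = C0 * V/F
#   C(t)  = X(t) / (V/F),  k_in = C0 * CL/F
# The dose-induced departure from baseline is a Bateman term, so
#   C(t) = C0 + dose*ka / (V/F * (ka - k_el)) * (exp(-k_el t) - exp(-ka t)).

# relative threshold below which ka ~ k_el is treated as confluent
.CONFLUENT_TOL <- 1e-8

#' @keywords internal
bateman_conc <- function(ka, k_el, v_f, c0, amount, t) {
  n <- max(length(t), length(amount))
  t <- rep_len(as.numeric(t), n)
  amount <- rep_len(as.numeric(amount), n)
  if (abs(ka - k_el) <= .CONFLUENT_TOL * max(ka, k_el)) {
    # confluent limit ka -> k_el of the Bateman function
    dep <- (amount / v_f) * ka * t * exp(-ka * t)
  } else {
    dep <- (amount * ka) / (v_f * (ka - k_el)) * (exp(-k_el * t) - exp(-ka * t))
  }
  c0 + dep
}

#' Model concentration-time curve (closed form)
#'
#' Serum concentration after a single oral dose on top of the endogenous
#' steady state. For all `t >= 0` the result is `>= c0`: the endogenous
#' baseline is a floor under a single superimposed dose.
#'
#' @param params [structural_params()].
#' @param dose [dose_event()] (or a single amount in mg).
#' @param t time(s) post dose, h; vectorized. Must be >= 0.
#' @return Concentration(s), mg/L.
#' @examples
#' p <- structural_params(1.89, 0.853, 5.1, 10, 0.243)
#' mi_concentration(p, dose_event(656), t = c(0, 1, 24))
#' @export
mi_concentration <- function(params, dose, t) {
  validate_structural_params(params)
  if (is.numeric(dose)) dose <- dose_event(dose)
  if (!inherits(dose, "dose_event")) stop("'dose' must be a dose_event",
                                          call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t))) stop("'t' must be finite numeric",
                                                 call. = FALSE)
  if (any(t < 0)) stop("negative times are outside the model domain",
                       call. = FALSE)
  bateman_conc(params$ka, params$cl_f / params$v_f, params$v_f, params$c0,
               dose$amount, t)
}

#' Right-hand side of the model ODE system
#'
#' Derivatives of the depot amount A and the central amount X, with the
#' endogenous input fixed by the steady-state constraint `k_in = c0 * cl_f`.
#'
#' @param state numeric of length 2: `c(A, X)`, amounts in mg.
#' @param params [structural_params()].
#' @return Named numeric `c(dA = dA/dt, dX = dX/dt)` in mg/h.
#' @export
ode_rhs <- function(state, params) {
  validate_structural_params(params)
  if (!is.numeric(state) || length(state) != 2L)
    stop("'state' must be numeric of length 2 (A, X)", call. = FALSE)
  A <- state[[1]]; X <- state[[2]]
  k_in <- params$c0 * params$cl_f
  k_el <- params$cl_f / params$v_f
  c(dA = -params$ka * A,
    dX = k_in - k_el * X + params$ka * A)
}

#' Numerical solution of the model ODE system
#'
#' Numerical twin of [mi_concentration()], integrating the two-compartment
#' balance with `deSolve::lsoda` from the initial state
#' `A(0) = dose, X(0) = c0 * v_f`. Used to validate the closed form and as
#' a hook for model extensions that lack one.
#'
#' @inheritParams mi_concentration
#' @param times sorted, non-negative output times, h.
#' @param rtol,atol solver tolerances passed to `deSolve::lsoda`.
#' @return Concentrations `X(t)/v_f` at `times`, mg/L.
#' @export
solve_ode <- function(params, dose, times, rtol = 1e-10, atol = 1e-10) {
  validate_structural_params(params)
  if (is.numeric(dose)) dose <- dose_event(dose)
  if (any(times < 0)) stop("negative times are outside the model domain",
                           call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  grid <- times
  prepend0 <- grid[1] > 0
  if (prepend0) grid <- c(0, grid)
  pad <- length(grid) < 2  # lsoda needs at least two time points
  if (pad) grid <- c(grid, grid[length(grid)] + 1)
  rhs <- function(t, y, parms) list(ode_rhs(y, parms))
  sol <- deSolve::lsoda(y = c(A = dose$amount, X = params$c0 * params$v_f),
                        times = grid, func = rhs, parms = params,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  x <- sol[, "X"]
  if (pad) x <- x[-length(x)]
  if (prepend0) x <- x[-1]
  unname(x) / params$v_f
}

#' Endogenous input rate from the steady-state constraint
#'
#' At the pre-dose steady state the zero-order endogenous input must balance
#' elimination: `k_in = c0 * cl_f` (mg/h).
#'
#' @param c0 endogenous steady-state concentration, mg/L (>= 0).
#' @param cl_f apparent clearance, L/h (> 0).
#' @return Endogenous input rate, mg/h.
#' @examples
#' steady_state_kin(10, 0.853)  # 8.53 mg/h
#' @export
steady_state_kin <- function(c0, cl_f) {
  stopifnot(is.numeric(c0), is.numeric(cl_f))
  if (any(c0 < 0)) stop("c0 must be >= 0", call. = FALSE)
  if (any(cl_f <= 0)) stop("cl_f must be > 0", call. = FALSE)
  c0 * cl_f
}

#' Time of the concentration peak
#'
#' Analytic maximum of the Bateman term: `ln(ka/k_el) / (ka - k_el)`,
#' reducing to `1/ka` in the confluent limit `ka = k_el`. The concentration
#' curve is strictly increasing before and strictly decreasing after it.
#'
#' @param params [structural_params()].
#' @return Peak time, h.
#' @export
mi_tmax <- function(params) {
  validate_structural_params(params)
  ka <- params$ka
  k_el <- params$cl_f / params$v_f
  if (abs(ka - k_el) <= .CONFLUENT_TOL * max(ka, k_el)) return(1 / ka)
  log(ka / k_el) / (ka - k_el)
}

#' Secondary pharmacokinetic parameters
#'
#' Derived quantities of the fitted model:
#' elimination rate constant `k_el = cl_f / v_f` (1/h), biological half-life
#' `t_half = ln(2)/k_el` (h), endogenous input rate `k_in = c0 * cl_f`
#' (mg/h), and the area under the concentration-time curve reported on the
#' weight-normalised dose scale, `auc = dose_per_kg / cl_f`.
#'
#' With `rounded = TRUE` the reporting chain of the original analysis is
#' reproduced: `k_el` is rounded to 2 decimals before the half-life is
#' computed, so published tables can be matched digit for digit. The default
#' is full precision.
#'
#' @param params [structural_params()].
#' @param dose_per_kg nominal dose, g/kg (> 0).
#' @param rounded logical; use the rounded reporting chain (default `FALSE`).
#' @return An object of class `secondary_params`: named list with `k_el`,
#'   `t_half`, `k_in`, `auc`, `dose_per_kg`.
#' @examples
#' p <- structural_params(1.89, 0.853, 5.1, 10, 0.243)
#' secondary_parameters(p, dose_per_kg = 2, rounded = TRUE)
#' @export
secondary_parameters <- function(params, dose_per_kg, rounded = FALSE) {
  validate_structural_params(params)
  if (!is.numeric(dose_per_kg) || length(dose_per_kg) != 1L ||
      !is.finite(dose_per_kg) || dose_per_kg <= 0)
    stop("dose_per_kg must be a single number > 0", call. = FALSE)
  k_el <- params$cl_f / params$v_f
  k_el_rep <- if (rounded) round(k_el, 2) else k_el
  out <- list(k_el = k_el_rep,
              t_half = log(2) / k_el_rep,
              k_in = steady_state_kin(params$c0, params$cl_f),
              auc = dose_per_kg / params$cl_f,
              dose_per_kg = dose_per_kg)
  class(out) <- "secondary_params"
  out
}

#' @export
print.secondary_params <- function(x, ...) {
  cat("Secondary PK parameters\n")
  cat(sprintf("  k_el   = %g 1/h        (elimination rate constant)\n", x$k_el))
  cat(sprintf("  t_half = %g h          (biological half-life)\n", x$t_half))
  cat(sprintf("  k_in   = %g mg/h       (endogenous input rate)\n", x$k_in))
  cat(sprintf("  AUC    = %g (g/kg)/(L/h) at %g g/kg\n", x$auc, x$dose_per_kg))
  invisible(x)
}
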