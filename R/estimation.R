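# Maximum-likelihood estimation under the proportional residual-error model
#   C_obs = C * (1 + eps),  eps ~ N(0, sigma^2)
# i.e. C_obs ~ Normal(Chat, sigma * Chat). All positive parameters are fit
# on the log scale so positivity holds by construction.

# bounds (log scale) and the floor that catches the sigma -> 0 boundary on
# noise-free data
.LOG_LOWER <- log(c(ka = 1e-8, cl_f = 1e-8, v_f = 1e-8, c0 = 1e-8,
                    sigma = 1e-6))
.LOG_UPPER <- log(c(ka = 1e8, cl_f = 1e8, v_f = 1e8, c0 = 1e8, sigma = 1e2))
.PAR_NAMES <- c("ka", "cl_f", "v_f", "c0", "sigma")

#' Negative log-likelihood of a dataset under the proportional-error model
#'
#' Sum over all observations of
#' `0.5*log(2*pi*sigma^2*Chat^2) + (C_obs - Chat)^2 / (2*sigma^2*Chat^2)`
#' where `Chat` is the model prediction at that subject's dose and time.
#'
#' @param params [structural_params()] with `sigma > 0`.
#' @param dataset [mi_dataset()].
#' @return The negative log-likelihood (scalar); finite whenever all
#'   predictions are positive.
#' @export
neg_log_likelihood <- function(params, dataset) {
  validate_structural_params(params)
  if (params$sigma <= 0) stop("sigma must be > 0 to evaluate the likelihood",
                              call. = FALSE)
  ot <- obs_table(dataset)
  nll_from_table(c(params$ka, params$cl_f, params$v_f, params$c0,
                   params$sigma), ot)
}

# hot path shared by neg_log_likelihood and the optimizer: theta on the
# natural scale, ot a flat obs_table
#' @keywords internal
nll_from_table <- function(theta, ot) {
  ka <- theta[1]; cl_f <- theta[2]; v_f <- theta[3]; c0 <- theta[4]
  sigma <- theta[5]
  pred <- bateman_conc(ka, cl_f / v_f, v_f, c0, ot$amount, ot$time)
  if (any(pred <= 0)) return(Inf)
  sd <- sigma * pred
  sum(0.5 * log(2 * pi * sd^2) + (ot$conc - pred)^2 / (2 * sd^2))
}

# "auto" initial values: c0 from pre-dose samples, k_el from the log-linear
# slope of the last 3 mean concentrations above c0, ka = 4*k_el,
# v_f from the peak departure, sigma = 0.2
#' @keywords internal
auto_init <- function(ot) {
  c0 <- if (any(ot$time == 0)) mean(ot$conc[ot$time == 0]) else min(ot$conc)
  mt <- tapply(ot$conc[ot$time > 0], ot$time[ot$time > 0], mean)
  tt <- as.numeric(names(mt))
  above <- mt > c0
  k_el <- 0.15
  if (sum(above) >= 2) {
    keep <- utils::tail(which(above), 3)
    y <- log(pmax(mt[keep] - c0, 1e-6))
    sl <- stats::coef(stats::lm(y ~ tt[keep]))[[2]]
    # accept the slope only when it implies a half-life shorter than twice
    # the observation span; late samples at baseline otherwise yield a
    # near-zero slope that strands every start in a flat-line local optimum
    if (is.finite(sl) && sl < 0 && -sl >= log(2) / (2 * max(tt))) k_el <- -sl
  }
  peak_dep <- max(ot$conc - c0, 1e-3)
  v_f <- mean(ot$amount) / (4 * peak_dep)
  structural_params(ka = 4 * k_el, cl_f = k_el * v_f, v_f = v_f,
                    c0 = max(c0, 1e-3), sigma = 0.2)
}

# run body with a private RNG state, restoring the caller's stream
#' @keywords internal
with_local_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body()
}

# The Bateman term is exactly symmetric under swapping ka and k_el with the
# volume rescaled (V' = V*k_el/ka): the likelihood has two equivalent global
# optima ("flip-flop"). Clearance, AUC and the curve itself are invariant;
# by the usual oral-PK convention we report the branch with absorption
# faster than elimination (ka > k_el), which the observed early peak and
# multi-hour terminal half-life support.
#' @keywords internal
canonical_branch <- function(lp) {
  th <- exp(lp)
  ka <- th[1]; cl <- th[2]; v <- th[3]
  k_el <- cl / v
  if (ka >= k_el) return(lp)
  v2 <- v * k_el / ka
  log(c(k_el, cl, v2, th[4], th[5]))
}

# central-difference gradient / Hessian on the log-parameter scale
#' @keywords internal
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @keywords internal
fd_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- numeric(n); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Fit the structural model to a concentration dataset
#'
#' Maximum-likelihood fit under the proportional residual-error model.
#' The primary mode is a naive-pooled typical-value fit: one parameter set
#' describes all subjects jointly (each with its own dose amount), matching
#' a report of typical values plus residual variance. `per-subject` fits
#' each animal separately.
#'
#' Optimization runs `stats::nlminb` on log-transformed parameters from
#' `n_starts` starting points (the initial guess plus multiplicatively
#' jittered copies), keeping the best likelihood. `converged` is `TRUE`
#' only when the optimizer reports success and the projected gradient
#' (ignoring components pinned at bounds) is small.
#'
#' The Bateman curve is invariant under exchanging `ka` and `k_el` with the
#' volume rescaled (flip-flop ambiguity), so the likelihood has two
#' equivalent optima; the fit reports the conventional branch with
#' absorption faster than elimination (`ka > k_el`). Apparent clearance,
#' AUC and all predictions are identical on either branch.
#'
#' @param dataset [mi_dataset()].
#' @param init [structural_params()] initial values, or `"auto"` (heuristics
#'   from baseline samples and the terminal slope).
#' @param mode `"pooled"` (default) or `"per-subject"`.
#' @param n_starts number of optimizer starts (default 8).
#' @param jitter multiplicative jitter half-width for the extra starts
#'   (default 0.5, i.e. factors uniform on `[0.5, 1.5]`).
#' @param start_seed seed for the (local) jitter stream; fits are
#'   deterministic given identical inputs.
#' @return For pooled mode, an object of class `mi_fit`: `estimates`
#'   ([structural_params()]), `cv_percent`, `loglik`, `n_obs`, `converged`,
#'   `covariance` (log scale), `fit_mode`, plus the dataset and diagnostics.
#'   For per-subject mode, class `mi_fit_list`: one `mi_fit` per subject.
#' @export
mi_fit <- function(dataset, init = "auto", mode = c("pooled", "per-subject"),
                   n_starts = 8, jitter = 0.5, start_seed = 20220924) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "mi_dataset"))
  if (mode == "per-subject") {
    fits <- lapply(dataset$subjects, function(s) {
      mi_fit(mi_dataset(list(s), study = s$subject_id,
                        units = dataset$metadata$units),
             init = init, mode = "pooled", n_starts = n_starts,
             jitter = jitter, start_seed = start_seed)
    })
    names(fits) <- vapply(dataset$subjects, `[[`, character(1), "subject_id")
    return(structure(list(fits = fits, fit_mode = "per-subject"),
                     class = "mi_fit_list"))
  }

  ot <- obs_table(dataset)
  if (!any(ot$time > 0))
    stop("unidentifiable: dataset has no post-dose observations ",
         "(no information on ka, cl_f, v_f)", call. = FALSE)

  if (identical(init, "auto")) init <- auto_init(ot)
  validate_structural_params(init)
  lp0 <- log(pmax(c(init$ka, init$cl_f, init$v_f, init$c0,
                    max(init$sigma, 0.05)), exp(.LOG_LOWER)))

  obj <- function(lp) nll_from_table(exp(lp), ot)

  starts <- with_local_seed(start_seed, function() {
    s <- matrix(rep(lp0, n_starts), nrow = n_starts, byrow = TRUE)
    if (n_starts > 1)
      for (k in 2:n_starts)
        s[k, ] <- lp0 + log(stats::runif(5, 1 - jitter, 1 + jitter))
    s
  })

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[k, ], obj, lower = .LOG_LOWER, upper = .LOG_UPPER,
                    control = list(eval.max = 2000, iter.max = 1500,
                                   rel.tol = 1e-10, x.tol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective) &&
        (is.null(best) || res$objective < best$objective)) best <- res
  }
  if (is.null(best))
    stop("optimizer failed on every start; check the dataset and initials",
         call. = FALSE)

  lp_hat <- canonical_branch(best$par)
  nll_hat <- best$objective
  grad <- fd_gradient(obj, lp_hat)
  at_bound <- lp_hat <= .LOG_LOWER + 1e-9 | lp_hat >= .LOG_UPPER - 1e-9
  gnorm <- max(abs(grad[!at_bound]), 0)

  H <- fd_hessian(obj, lp_hat, h = 1e-4)
  cov <- tryCatch({
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) NULL else solve(H)
  }, error = function(e) NULL)
  if (!is.null(cov)) dimnames(cov) <- list(.PAR_NAMES, .PAR_NAMES)

  # Noise-free data drive sigma to its floor, where the curvature scales as
  # 1/sigma^2 and finite-difference gradients/Hessians are meaningless:
  # detect that perfect-fit boundary directly from the residuals.
  theta_hat <- exp(lp_hat)
  pred_hat <- bateman_conc(theta_hat[1], theta_hat[2] / theta_hat[3],
                           theta_hat[3], theta_hat[4], ot$amount, ot$time)
  perfect_fit <- theta_hat[5] <= 1.01 * exp(.LOG_LOWER[["sigma"]]) &&
    max(abs(ot$conc - pred_hat) / pred_hat) < 1e-4

  # first-order optimality, scale-aware: the Newton decrement g'H^{-1}g/2
  # bounds the attainable likelihood improvement. Falls back to the
  # projected gradient when the observed information is not positive
  # definite.
  newton_dec <- if (!is.null(cov))
    0.5 * drop(grad %*% cov %*% grad) else Inf
  converged <- is.finite(nll_hat) &&
    (perfect_fit || newton_dec < 1e-4 ||
       gnorm < 1e-3 * (1 + abs(nll_hat)))

  est <- structural_params(theta_hat[1], theta_hat[2], theta_hat[3],
                           theta_hat[4], theta_hat[5])
  fit <- structure(list(estimates = est,
                        log_estimates = stats::setNames(lp_hat, .PAR_NAMES),
                        loglik = -nll_hat,
                        n_obs = nrow(ot),
                        converged = converged,
                        covariance = cov,
                        fit_mode = "pooled",
                        perfect_fit = perfect_fit,
                        gradient_norm = gnorm,
                        optimizer = list(convergence = best$convergence,
                                         message = best$message,
                                         iterations = best$iterations),
                        dataset = dataset),
                   class = "mi_fit")
  fit$cv_percent <- tryCatch(asymptotic_cv(fit), warning = function(w) {
    stats::setNames(rep(NA_real_, 6),
                    c(.PAR_NAMES, "sigma2"))
  })
  fit
}

#' Asymptotic coefficients of variation of a fit
#'
#' Precision from the observed information: the covariance of the
#' log-parameters is the inverse finite-difference Hessian of the negative
#' log-likelihood at the optimum. For a log-scale parameter with variance
#' `v`, CV% = `100*sqrt(exp(v) - 1)`. The residual variance `sigma^2`
#' (log-scale variance `4v_sigma`) is reported alongside.
#'
#' @param fit an `mi_fit`.
#' @return Named numeric of CV% for `ka`, `cl_f`, `v_f`, `c0`, `sigma`,
#'   `sigma2`; all `NA` (with a warning) when the Hessian is not positive
#'   definite.
#' @export
asymptotic_cv <- function(fit) {
  stopifnot(inherits(fit, "mi_fit"))
  if (!isTRUE(fit$converged))
    warning("fit did not converge; CVs are unreliable", call. = FALSE)
  if (isTRUE(fit$perfect_fit))
    # residuals vanish and sigma sits at its floor: the observed
    # information diverges, so the asymptotic CVs tend to zero
    return(stats::setNames(rep(0, 6), c(.PAR_NAMES, "sigma2")))
  if (is.null(fit$covariance)) {
    warning("observed information is not positive definite; ",
            "precision unavailable", call. = FALSE)
    return(stats::setNames(rep(NA_real_, 6), c(.PAR_NAMES, "sigma2")))
  }
  v <- diag(fit$covariance)
  cv <- 100 * sqrt(exp(v) - 1)
  sigma2_cv <- 100 * sqrt(exp(4 * v[["sigma"]]) - 1)
  stats::setNames(c(cv, sigma2_cv), c(.PAR_NAMES, "sigma2"))
}

#' Predicted concentrations for one subject of a fit
#'
#' @param object an `mi_fit`.
#' @param subject_id id of a subject present in the fitted dataset.
#' @param times times at which to predict, h; defaults to the subject's
#'   observation times.
#' @param ... unused.
#' @return Concentrations, mg/L.
#' @export
predict.mi_fit <- function(object, subject_id, times = NULL, ...) {
  ids <- vapply(object$dataset$subjects, `[[`, character(1), "subject_id")
  i <- match(as.character(subject_id), ids)
  if (is.na(i)) stop("unknown subject '", subject_id, "'", call. = FALSE)
  s <- object$dataset$subjects[[i]]
  if (is.null(times)) times <- s$times
  mi_concentration(object$estimates, s$dose, times)
}

#' @export
print.mi_fit <- function(x, ...) {
  cat(sprintf("Pooled ML fit: %d observations, logLik %.3f, converged: %s\n",
              x$n_obs, x$loglik, x$converged))
  est <- x$estimates; cv <- x$cv_percent
  lab <- c(ka = "1/h", cl_f = "L/h", v_f = "L", c0 = "mg/L", sigma = "")
  for (p in .PAR_NAMES)
    cat(sprintf("  %-5s = %-9.4g (CV %.1f%%) %s\n", p, est[[p]], cv[[p]],
                lab[[p]]))
  invisible(x)
}
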