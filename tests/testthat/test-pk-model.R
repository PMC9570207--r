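# Structural model: closed form, ODE twin, secondary parameters.

test_that("parameter and dose validation rejects out-of-domain values", {
  expect_error(structural_params(-1, 0.853, 5.1, 10), "ka")
  expect_error(structural_params(1.89, 0, 5.1, 10), "cl_f")
  expect_error(structural_params(1.89, 0.853, 5.1, -1), "c0")
  expect_error(structural_params(1.89, 0.853, 5.1, 10, -0.1), "sigma")
  expect_error(dose_event(-5), "amount")
  expect_error(dose_event(100, time = 1), "time 0")
  expect_equal(dose_event(dose_per_kg = 2, body_weight = 328)$amount, 656)
})

test_that("zero dose leaves the endogenous steady state unperturbed", {
  p <- ref_params()
  tt <- c(0, 0.5, 1, 24, 48, 96)
  expect_equal(mi_concentration(p, dose_event(0), tt), rep(10, length(tt)))
  expect_equal(solve_ode(p, dose_event(0), c(0, 24, 48)), rep(10, 3),
               tolerance = 1e-8)
})

test_that("concentration starts at the baseline and rejects negative times", {
  p <- ref_params()
  expect_equal(mi_concentration(p, dose_event(656), 0), 10)
  expect_equal(solve_ode(p, dose_event(656), 0), 10)
  expect_error(mi_concentration(p, dose_event(656), -1), "negative")
})

test_that("closed form matches the high-accuracy ODE oracle at 1 h", {
  # frozen from lsoda at rtol = atol = 1e-12 (dose 2 g/kg x 328 g = 656 mg)
  p <- ref_params()
  expect_equal(mi_concentration(p, dose_event(656), 1), 108.062811,
               tolerance = 1e-6)
  expect_equal(solve_ode(p, dose_event(656), c(0, 1))[2], 108.062811,
               tolerance = 1e-6)
})

test_that("ODE right-hand side matches hand arithmetic", {
  p <- ref_params()
  # endogenous steady state is an equilibrium
  expect_equal(unname(ode_rhs(c(0, 10 * 5.1), p)), c(0, 0))
  # dA/dt = -ka * A
  expect_equal(ode_rhs(c(100, 0), p)[["dA"]], -189)
  # dX/dt = k_in - k_el*X + ka*A; k_el*51 = 8.53 cancels k_in exactly
  expect_equal(ode_rhs(c(656, 51), p)[["dX"]], 8.53 - (0.853 / 5.1) * 51 +
                 1.89 * 656)
  expect_equal(ode_rhs(c(656, 51), p)[["dX"]], 1239.84)
  expect_error(ode_rhs(c(1, 2, 3), p), "length 2")
})

test_that("closed form and ODE solution agree on a dense grid", {
  p <- ref_params()
  tt <- seq(0, 48, by = 0.25)
  cf <- mi_concentration(p, dose_event(656), tt)
  od <- solve_ode(p, dose_event(656), tt)
  expect_lt(max(abs(od - cf) / cf), 1e-6)
})

test_that("secondary parameters reproduce the published rounding chain", {
  p <- ref_params()
  s <- secondary_parameters(p, dose_per_kg = 2, rounded = TRUE)
  expect_equal(round(s$k_el, 2), 0.17)
  expect_equal(round(s$t_half, 2), 4.08)
  expect_equal(round(s$k_in, 2), 8.53)
  expect_equal(round(s$auc, 2), 2.34)
  # full precision half-life uses the unrounded k_el
  sf <- secondary_parameters(p, dose_per_kg = 2)
  expect_equal(sf$k_el, 0.853 / 5.1)
  expect_equal(sf$t_half, log(2) * 5.1 / 0.853)
  expect_error(secondary_parameters(p, dose_per_kg = 0), "dose_per_kg")
})

test_that("steady-state input rate balances elimination of the baseline", {
  expect_equal(steady_state_kin(10, 0.853), 8.53)
  expect_equal(steady_state_kin(0, 1.7), 0)
  expect_equal(steady_state_kin(20, 0.5), 10)
  expect_error(steady_state_kin(10, 0), "cl_f")
  expect_error(steady_state_kin(-1, 1), "c0")
})

test_that("analytic peak time matches a grid search of the curve", {
  p <- ref_params()
  tm <- mi_tmax(p)
  expect_equal(tm, log(1.89 / (0.853 / 5.1)) / (1.89 - 0.853 / 5.1))
  tg <- seq(0, 48, by = 0.001)
  tm_grid <- tg[which.max(mi_concentration(p, dose_event(656), tg))]
  expect_equal(tm, tm_grid, tolerance = 1e-3)
  # confluent limit ka = k_el = k peaks at 1/k
  pc <- structural_params(0.4, 0.4 * 5, 5, 10, 0)
  expect_equal(mi_tmax(pc), 1 / 0.4)
  # instantaneous absorption peaks immediately
  pf <- structural_params(1e6, 0.853, 5.1, 10, 0)
  expect_lt(mi_tmax(pf), 1e-4)
})

test_that("curve rises to the peak, falls after it, and returns to baseline", {
  p <- ref_params()
  d <- dose_event(656)
  tm <- mi_tmax(p)
  up <- mi_concentration(p, d, seq(0, tm, length.out = 200))
  dn <- mi_concentration(p, d, seq(tm, 96, length.out = 200))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) < 0))
  expect_true(all(mi_concentration(p, d, seq(0, 96, 0.5)) >= 10))
  # the departure from baseline vanishes in the terminal phase: down to
  # ~2^-10 of the exponential amplitude by 10 half-lives and below 0.1%
  # of the peak departure by 11 half-lives
  t_half <- log(2) / (0.853 / 5.1)
  peak_dep <- mi_concentration(p, d, tm) - 10
  late_dep <- mi_concentration(p, d, 11 * t_half) - 10
  expect_lt(late_dep / peak_dep, 0.001)
  expect_lt(mi_concentration(p, d, 10 * t_half) - 10, 0.0015 * peak_dep)
})

test_that("general formula is continuous into the confluent limit", {
  k <- 0.3
  v <- 5
  c0 <- 10
  lim <- structural_params(k, k * v, v, c0, 0)
  near <- structural_params(k * (1 + 1e-7), k * v, v, c0, 0)
  tt <- seq(0, 48, by = 0.5)
  expect_equal(mi_concentration(near, dose_event(600), tt),
               mi_concentration(lim, dose_event(600), tt), tolerance = 1e-6)
})

test_that("allometric scaling is identity at the reference weight", {
  p <- ref_params()
  expect_equal(allometric_scale(p, 320, 320), p)
  ps <- allometric_scale(p, 640, 320)
  expect_equal(ps$cl_f, 0.853 * 2^0.75)
  expect_equal(ps$v_f, 5.1 * 2)
  expect_equal(ps$c0, 10)
})
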