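test_that("derived equilibrium quantities follow their definitions", {
  # a 1:199 split leaves half a percent in the binding-competent state
  eq <- derive_equilibrium(rate_constants(1, 199, 1e6, 0.01))
  expect_equal(eq$f_y, 0.005)
  # symmetric rates
  expect_equal(derive_equilibrium(rate_constants(5, 5, 1e6, 1))$f_y, 0.5)
  # conformational penalty dilutes the intrinsic affinity 200-fold
  eq2 <- derive_equilibrium(rate_constants(1, 199, 1e6, 0.01))
  expect_equal(eq2$k_d_intrinsic, 1e-8)
  expect_equal(eq2$k_d_app, 2e-6)
  # edge cases
  eq3 <- derive_equilibrium(rate_constants(3, 0, 1e6, 0.01))
  expect_equal(eq3$k_conf, Inf)
  expect_equal(eq3$f_y, 1)
  eq4 <- derive_equilibrium(rate_constants(1, 1, 0, 0.01))
  expect_false(eq4$kd_defined)
  expect_true(is.na(eq4$k_d_intrinsic))
})

test_that("rate constants are validated", {
  expect_error(rate_constants(-1, 1, 1, 1), "finite and >= 0")
  expect_error(rate_constants(0, 0, 1, 1), "k1 \\+ k_m1")
})

test_that("equilibrium populations satisfy the coupled equilibria", {
  r <- rate_constants(10, 1990, 1e6, 0.01)
  eq <- derive_equilibrium(r)
  st <- equilibrium_populations(r, 5e-8, 2e-7)
  # detailed balance: y/x = K_conf, yp/(y p) = 1/K_D within 1e-9
  expect_equal(st$y / st$x, eq$k_conf, tolerance = 1e-9)
  expect_equal(st$yp / (st$y * st$p), 1 / eq$k_d_intrinsic, tolerance = 1e-9)
  # conservation
  expect_equal(st$x + st$y + st$yp, 5e-8, tolerance = 1e-12)
  expect_equal(st$p + st$yp, 2e-7, tolerance = 1e-12)
  # k2 = 0 decouples binding
  st0 <- equilibrium_populations(rate_constants(10, 1990, 0, 0.01), 1e-6, 1e-6)
  expect_equal(st0$yp, 0)
  expect_equal(st0$y / st0$x, 10 / 1990, tolerance = 1e-12)
  # saturation limit
  sts <- equilibrium_populations(r, 1e-9, 1e-3)
  expect_equal(sts$yp, 1e-9, tolerance = 1e-4)
})

test_that("equilibrium populations agree with the long-time ODE limit", {
  set.seed(81)
  for (i in 1:5) {
    r <- rate_constants(10^runif(1, 0, 2), 10^runif(1, 0, 3),
                        10^runif(1, 4, 7), 10^runif(1, -3, -1))
    h <- 10^runif(1, -9, -7); p <- 10^runif(1, -8, -6)
    st <- equilibrium_populations(r, h, p)
    rates_min <- min(r$k1 + r$k_m1, r$k2 * p + r$k_m2)
    tr <- simulate_kinetics(r, kinetic_state(x = h, p = p),
                            c(0, 1e4 / rates_min))
    last <- tr[nrow(tr), ]
    expect_equal(last$x, st$x, tolerance = 1e-6)
    expect_equal(last$yp, st$yp, tolerance = 1e-6)
  }
})

test_that("the ODE respects conservation and closed-form two-state relaxation", {
  # k2 = 0: pure conformational relaxation at rate k1 + k_m1
  r <- rate_constants(2, 6, 0, 0)
  h <- 1e-6
  tg <- seq(0, 2, length.out = 50)
  tr <- simulate_kinetics(r, kinetic_state(x = h), tg)
  f_y <- 0.25
  closed <- h * ((1 - f_y) + f_y * exp(-(2 + 6) * tg))
  expect_equal(tr$x, closed, tolerance = 1e-6)
  # conservation along a binding trajectory
  r2 <- rate_constants(10, 1990, 1e6, 0.01)
  tr2 <- simulate_kinetics(r2, kinetic_state(x = 5e-8, p = 2e-7),
                           c(0, 10^seq(-4, 3, length.out = 60)))
  expect_lt(max(abs((tr2$x + tr2$y + tr2$yp) / 5e-8 - 1)), 1e-9)
  expect_lt(max(abs((tr2$p + tr2$yp) / 2e-7 - 1)), 1e-9)
  # degenerate grid returns the initial state
  tr3 <- simulate_kinetics(r2, kinetic_state(x = 1e-9, p = 1e-8), 0)
  expect_equal(nrow(tr3), 1)
  expect_equal(tr3$x, 1e-9)
  expect_error(simulate_kinetics(r2, list(x = -1e-9, y = 0, yp = 0, p = 0),
                                 c(0, 1)), "negative")
})

test_that("analytic excess-peptide solution matches the ODE and its regimes", {
  # null dynamics
  r0 <- rate_constants(0, 1, 0, 0)
  tr0 <- linear_solution_excess_p(r0, 1e-6, kinetic_state(x = 1e-8), seq(0, 10, 1))
  expect_true(all(tr0$x == 1e-8 & tr0$y == 0 & tr0$yp == 0))
  # timescale separation: slow eigenvalue ~ k2 F_Y p + k_m2 within 1%
  r <- rate_constants(10, 1990, 1e6, 0.01) # (k1+k_m1)/(k2 p + k_m2) = 1980
  p0 <- 1e-6
  tr <- linear_solution_excess_p(r, p0, kinetic_state(x = 2e-9), seq(0, 100, 1))
  slow <- attr(tr, "eigenvalues")[2]
  expect_equal(slow, 1e6 * 0.005 * p0 + 0.01, tolerance = 0.01)
  # without separation the trace is visibly bi-exponential
  fit_resid <- function(rates, p0, t_end) {
    f_y <- derive_equilibrium(rates)$f_y
    tg <- seq(0, t_end, length.out = 120)
    tr <- linear_solution_excess_p(rates, p0,
                                   kinetic_state(x = (1 - f_y) * 2e-9,
                                                 y = f_y * 2e-9), tg)
    ft <- fit_exponential(data.frame(time = tg, signal = tr$x / 2e-9))
    ft$residual_rms / abs(ft$params$amplitude)
  }
  sep <- fit_resid(r, 1e-6, 400)
  mixed <- fit_resid(rate_constants(1, 1, 1e6, 0.5), 1e-6, 5)
  expect_gt(mixed, 10 * sep)
})

test_that("pre-equilibrium on-rate is k2 * F_Y with a validity flag", {
  # half-percent occupancy: the design regime of slow observed association
  k <- pre_equilibrium_kon(rate_constants(78, 922, 1e6, 0.01), p_ref = 1e-6)
  expect_equal(k$k_on, 7.8e4)
  expect_true(k$valid)
  k2 <- pre_equilibrium_kon(rate_constants(10, 3990, 1e6, 0.01))
  expect_equal(k2$k_on, 2.5e3)
  # locked-Y limit
  kl <- pre_equilibrium_kon(lock_state(rate_constants(10, 1990, 1e6, 0.01), "Y"))
  expect_equal(kl$k_on, 1e6)
  # invalid when binding is as fast as the conformational exchange
  kf <- pre_equilibrium_kon(rate_constants(1, 1, 1e6, 0.01), p_ref = 1e-4)
  expect_false(kf$valid)
})

test_that("stability shifts scale K_conf by exp(ddG/RT) under both conventions", {
  r <- rate_constants(10, 1990, 1e6, 0.01)
  rt <- 1.98720425e-3 * 298.15
  up <- apply_stability_shift(r, rt * log(22))
  expect_equal((up$k1 / up$k_m1) / (r$k1 / r$k_m1), 22, tolerance = 1e-12)
  expect_equal(up$k1, r$k1) # scale_km1 leaves k1 alone
  up2 <- apply_stability_shift(r, rt * log(22), convention = "scale_k1")
  expect_equal((up2$k1 / up2$k_m1) / (r$k1 / r$k_m1), 22, tolerance = 1e-12)
  expect_equal(up2$k_m1, r$k_m1)
  # in the rare-Y regime the on-rate rises by (nearly) the same fold change;
  # the residual saturation of F_Y sets the deviation
  rr <- rate_constants(1, 4999, 1e6, 0.01) # F_Y = 2e-4
  fold <- pre_equilibrium_kon(apply_stability_shift(rr, rt * log(22)))$k_on /
    pre_equilibrium_kon(rr)$k_on
  expect_equal(fold, 22, tolerance = 0.01)
  # identity and inverse
  expect_equal(unclass(apply_stability_shift(r, 0)), unclass(r))
  back <- apply_stability_shift(apply_stability_shift(r, -rt * log(22)),
                                rt * log(22))
  expect_equal(back$k_m1 / r$k_m1, 1, tolerance = 1e-12)
})

test_that("locking a state removes the opposing conformational flux", {
  r <- rate_constants(10, 1990, 1e6, 0.01)
  # locked X never binds
  lx <- lock_state(r, "X")
  stx <- equilibrium_populations(lx, 1e-6, 1e-3)
  expect_equal(stx$yp, 0)
  # locked Y binds with the full microscopic rate
  expect_equal(pre_equilibrium_kon(lock_state(r, "Y"))$k_on, r$k2)
  # breaking the staple restores the apparent affinity
  eq <- derive_equilibrium(r)
  expect_equal(eq$k_d_app, eq$k_d_intrinsic / eq$f_y)
})

test_that("competition with excess unlabeled hinge strips the labeled complex", {
  r <- rate_constants(50, 50, 1e6, 0.01) # F_Y = 0.5, K_D,app 20 nM
  h_lab <- 30e-9; p_tot <- 200e-9; h_comp <- 100 * p_tot # 100x over the peptide
  tg <- seq(0, 40000, length.out = 200)
  sched <- list(t_peptide = 0, t_competitor = 3600)
  tr <- simulate_competition(r, r, h_lab, p_tot, h_comp, sched, tg)
  # before the chase the labeled hinge is mostly bound
  pre <- tr[max(which(tr$time <= 3600)), ]
  expect_gt(pre$yp / h_lab, 0.8)
  # at steady state the labeled bound fraction is < 2 percent
  post <- tr[nrow(tr), ]
  expect_lt(post$yp / h_lab, 0.02)
  # and the labeled free-state population returns to the pre-peptide level
  expect_equal(post$x / ((1 - 0.5) * h_lab), 1, tolerance = 0.05)
  # reduction: no competitor reproduces simulate_kinetics
  tr0 <- simulate_competition(r, r, h_lab, p_tot, 0, sched, tg)
  f_y <- 0.5
  ref <- simulate_kinetics(r, kinetic_state(x = (1 - f_y) * h_lab,
                                            y = f_y * h_lab, p = p_tot), tg)
  expect_equal(tr0$yp, ref$yp, tolerance = 1e-6)
  # an inert competitor (k2 = 0) leaves the labeled trace unchanged
  tri <- simulate_competition(r, rate_constants(50, 50, 0, 0), h_lab, p_tot,
                              h_comp, sched, tg)
  expect_equal(tri$yp, ref$yp, tolerance = 1e-6)
})
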