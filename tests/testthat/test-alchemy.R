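test_that("lambda legs enforce grid invariants", {
  expect_error(lambda_leg("vdw", c(0, 0.5), c(1, 1)), "endpoints")
  expect_error(lambda_leg("vdw", c(0, 0.5, 0.4, 1), rep(1, 4)), "increasing")
  expect_error(lambda_leg("vdw", c(-0.1, 0.5, 1), rep(1, 3)), "\\[0, 1\\]")
  expect_error(lambda_leg("vdw", c(0, 1), c(1, 1), dvdl_sem = -1), ">= 0")
})

test_that("TI integration is exact on constants and lines", {
  lam <- c(0, 0.1, 0.35, 0.6, 1)
  leg_c <- lambda_leg("vdw", lam, rep(4.2, 5))
  expect_equal(ti_integrate(leg_c)$dF, 4.2)
  leg_l <- lambda_leg("vdw", lam, 2 * lam)
  expect_equal(ti_integrate(leg_l)$dF, 1.0)
  # grid refinement does not change a linear profile's integral
  lam2 <- seq(0, 1, length.out = 101)
  expect_equal(ti_integrate(lambda_leg("vdw", lam2, 2 * lam2))$dF, 1.0)
})

test_that("trapezoid and Simpson converge at their textbook orders", {
  # quadratic: trapezoid error within composite bound, Simpson exact
  lam37 <- seq(0, 1, length.out = 37)
  leg_q <- lambda_leg("vdw", lam37, 3 * lam37^2)
  expect_lt(abs(ti_integrate(leg_q)$dF - 1.0), 5e-4)
  expect_equal(ti_integrate(leg_q, "simpson")$dF, 1.0, tolerance = 1e-12)

  # empirical order: halving h divides the trapezoid error by ~4
  err_at <- function(n) {
    l <- seq(0, 1, length.out = n)
    abs(ti_integrate(lambda_leg("vdw", l, 3 * l^2))$dF - 1)
  }
  expect_equal(err_at(11) / err_at(21), 4, tolerance = 0.1)

  # quartic: Simpson error falls ~16x per halving
  err_s <- function(n) {
    l <- seq(0, 1, length.out = n)
    abs(ti_integrate(lambda_leg("vdw", l, 5 * l^4), "simpson")$dF - 1)
  }
  expect_equal(err_s(11) / err_s(21), 16, tolerance = 0.15)

  expect_error(ti_integrate(lambda_leg("vdw", c(0, 0.3, 1), rep(1, 3)),
                            "simpson"), "uniform")
})

test_that("binding free energy sums legs and guards tension states", {
  lam <- seq(0, 1, length.out = 11)
  mk <- function(leg, val, state) lambda_leg(leg, lam, rep(val, 11),
                                             tension_state = state)
  ti0 <- binding_free_energy(mk("vdw", 0, "A0"), mk("coulomb", 0, "A0"))
  expect_equal(ti0$dF_total, 0)
  ti <- binding_free_energy(mk("vdw", -100, "A"), mk("coulomb", -20, "A"))
  expect_equal(ti$dF_total, -120)
  expect_equal(unname(ti$dF_per_leg), c(-100, -20))
  expect_error(binding_free_energy(mk("vdw", 1, "A0"), mk("coulomb", 1, "A")),
               "different tension states")
})

test_that("alchemical sensing subtracts states with label guards", {
  lam <- seq(0, 1, length.out = 11)
  mk <- function(val, state)
    binding_free_energy(lambda_leg("vdw", lam, rep(0.6 * val, 11),
                                   tension_state = state),
                        lambda_leg("coulomb", lam, rep(0.4 * val, 11),
                                   tension_state = state))
  expect_equal(alchemical_sensing(mk(-100, "A"), mk(-100, "A0"))$ddF, 0)
  expect_equal(alchemical_sensing(mk(-120, "A"), mk(-100, "A0"))$ddF, -20)
  expect_error(alchemical_sensing(mk(-100, "A0"), mk(-120, "A")), "stretched")
})

test_that("synthetic TI legs integrate to their targets and close the cycle", {
  mp <- hookean_model(dA_p = 0.5, softening = 1, noise_amp = 0)
  spec <- cycle_spec(mp, 49.4)
  legs0 <- simulate_dhdl(spec, "A0")
  ti0 <- binding_free_energy(legs0$vdw, legs0$coulomb)
  expect_equal(ti0$dF_total, -100, tolerance = 1e-6)   # solvation + W_bind
  legsA <- simulate_dhdl(spec, "A")
  tiA <- binding_free_energy(legsA$vdw, legsA$coulomb)
  sens <- alchemical_sensing(tiA, ti0)
  expect_equal(sens$ddF, ddF_closed_form(mp, 7), tolerance = 1e-3)
})

test_that("Welch cycle closure matches a textbook hand computation", {
  ref <- stretch_curve(42.4, c(42.4, 49.4),
                       estimates = NULL, sigma = c(0, 20), sem = c(1, 1))
  pep <- stretch_curve(42.4, c(42.4, 49.4), sigma = c(-2, 12), sem = c(1, 1))
  mech <- sensing_free_energy(pep, ref)

  # identical means with equal nonzero errors: t = 0, p = 1, closed
  cc0 <- cycle_closure(mech, list(ddF = mech$ddF, err = mech$ddF_err), 3, 3)
  expect_equal(cc0$t, 0)
  expect_equal(cc0$p, 1)
  expect_true(cc0$closed)

  # means several combined sems apart, n = 3 vs 3: Welch formula as oracle
  se1 <- mech$ddF_err; se2 <- 1.5
  delta <- 6 * sqrt(se1^2 + se2^2)
  cc <- cycle_closure(mech, list(ddF = mech$ddF - delta, err = se2), 3, 3)
  t_hand <- delta / sqrt(se1^2 + se2^2)
  df_hand <- (se1^2 + se2^2)^2 / (se1^4 / 2 + se2^4 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(cc$t, t_hand)
  expect_equal(cc$df, df_hand)
  expect_equal(cc$p, p_hand)
  expect_false(cc$closed)

  # degenerate zero-variance branch
  ref0 <- stretch_curve(42.4, c(42.4, 49.4), sigma = c(0, 20))
  mech0 <- sensing_free_energy(ref0, ref0)
  ccz <- cycle_closure(mech0, list(ddF = 1, err = 0), 3, 3)
  expect_false(ccz$closed)
  expect_true(is.na(ccz$p))
  expect_error(cycle_closure(mech, list(ddF = 0, err = 1), 1, 3), ">= 2")
})

test_that("cycle consistency holds on synthetic data, noiseless and noisy", {
  mp <- hookean_model(dA_p = 0.5, softening = 0.9, noise_amp = 0)
  cyc <- synthetic_cycle(mp, ti_noise = 0)
  expect_lt(abs(cyc$mech$ddF - cyc$alch$ddF), 1e-9)

  mpn <- hookean_model(dA_p = 0.5, softening = 0.9)
  closed <- vapply(1:20, function(s)
    synthetic_cycle(mpn, seed = s)$closure$closed, logical(1))
  expect_gte(sum(closed), 18)
})
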