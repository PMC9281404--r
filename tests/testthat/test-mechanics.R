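test_that("relative strain matches the stretching protocol arithmetic", {
  expect_equal(relative_strain(49.4, 42.4), 7 / 42.4)
  expect_equal(round(100 * relative_strain(49.4, 42.4), 1), 16.5)
  expect_equal(relative_strain(42.4, 42.4), 0)
  expect_equal(relative_strain(84.8, 42.4), 1)
  expect_error(relative_strain(42.4, 0), "positive")
})

test_that("stretch-curve invariants are enforced", {
  expect_error(stretch_curve(42.4, c(43, 44), c(1, 2)), "A0")
  expect_error(stretch_curve(42.4, c(42.4, 42.4), c(1, 2)), "distinct")
  expect_error(stretch_curve(42.4, 42.4, 1), "two points")
  cur <- stretch_curve(42.4, c(49.4, 42.4), c(25, 0))  # sorted on input
  expect_equal(cur$area, c(42.4, 49.4))
  expect_equal(cur$strain, c(0, 7 / 42.4))
})

test_that("area compressibility fit recovers exact and noisy slopes", {
  # exact two-point line through the origin
  cur <- stretch_curve(40, c(40, 44), sigma = c(0, 300 * 0.1))
  expect_equal(fit_area_compressibility(cur)$K_A, 300)

  # noiseless synthetic curve: K_A recovered to machine precision
  m <- hookean_model(K_A = 240, noise_amp = 0)
  cs <- generate_stretch_curves(m, m, n_frames = 10)
  fit <- fit_area_compressibility(cs$reference)
  expect_equal(fit$K_A, 240, tolerance = 1e-12)

  # noisy curve: truth within 2 standard errors at a fixed seed
  mn <- hookean_model(K_A = 240, noise_amp = 60)
  csn <- generate_stretch_curves(mn, mn, n_frames = 4000, seed = 42)
  fitn <- fit_area_compressibility(csn$reference)
  expect_lt(abs(fitn$K_A - 240), 2 * fitn$se)

  flat <- stretch_curve(40, c(40, 44), c(0, 1))
  flat$strain <- c(0, 0)
  expect_error(fit_area_compressibility(flat), "slope")
})

test_that("stretch work evaluates the trapezoid with unit conversion", {
  expect_equal(stretch_work(0, 0, 42.4, 49.4)$dF, 0)

  w <- stretch_work(0, 20, 42.4, 49.4)
  expect_equal(w$dF_mNm_nm2, 70)
  expect_equal(w$dF, 42.2, tolerance = 0.05)      # 70 * 0.6022
  expect_equal(w$dF, mN_m_nm2_to_kJ_mol(70))

  # swapping end states negates the work
  expect_equal(stretch_work(20, 0, 49.4, 42.4)$dF, -w$dF)
  expect_error(stretch_work(0, 20, 42.4, 42.4), "differ")

  # errors combine in quadrature
  w2 <- stretch_work(tension_estimate(0, 1), tension_estimate(20, 2),
                     42.4, 49.4)
  expect_equal(w2$err, mN_m_nm2_to_kJ_mol(7 / 2 * sqrt(5)))
})

test_that("multipoint work reduces to the end-state trapezoid on lines", {
  A0 <- 42.4
  areas <- seq(42.4, 49.4, by = 1.4)
  lin <- stretch_curve(A0, areas, sigma = 5.2 * (areas - A0))
  mp <- stretch_work_multipoint(lin)
  es <- stretch_work(lin$sigma[1], lin$sigma[6], A0, 49.4)
  expect_equal(mp$dF, es$dF, tolerance = 1e-12)

  # quadratic curve: composite trapezoid within its analytic error bound
  quad <- stretch_curve(A0, areas, sigma = 0.8 * (areas - A0)^2)
  exact <- mN_m_nm2_to_kJ_mol(0.8 * 7^3 / 3)
  h <- 1.4
  bound <- mN_m_nm2_to_kJ_mol(7 * h^2 / 12 * 2 * 0.8)
  expect_lt(abs(stretch_work_multipoint(quad)$dF - exact), bound * 1.0001)

  # single interval: identical to stretch_work by definition
  two <- stretch_curve(A0, c(42.4, 49.4), sigma = c(0, 20))
  expect_equal(stretch_work_multipoint(two)$dF,
               stretch_work(0, 20, 42.4, 49.4)$dF)
})

test_that("sensing free energy matches hand evaluation and the work identity", {
  A0 <- 42.4; A <- 49.4
  ref <- stretch_curve(A0, c(A0, A), sigma = c(0, 20))
  pep <- stretch_curve(A0, c(A0, A), sigma = c(-2, 12))
  res <- sensing_free_energy(pep, ref, mode = "end_state")
  expect_equal(kJ_mol_to_mN_m_nm2(res$ddF), 3.5 * -10)
  expect_equal(res$ddF, -21.1, tolerance = 0.05)

  # identity: end-state form equals the difference of independent works
  wp <- stretch_work(-2, 12, A0, A)
  wr <- stretch_work(0, 20, A0, A)
  expect_equal(res$ddF, wp$dF - wr$dF, tolerance = 1e-12)

  # identical curves: no sensing
  res0 <- sensing_free_energy(ref, ref)
  expect_equal(res0$ddF, 0)
  expect_equal(res0$chaos, 0)

  # mismatched reference areas are rejected
  pep2 <- stretch_curve(43, c(43, 49.4), sigma = c(-2, 12))
  expect_error(sensing_free_energy(pep2, ref), "A0")
  # mismatched grids rejected in multi_point mode
  ref3 <- stretch_curve(A0, c(A0, 45, A), sigma = c(0, 10, 20))
  pep3 <- stretch_curve(A0, c(A0, 46, A), sigma = c(-2, 5, 12))
  expect_error(sensing_free_energy(pep3, ref3, mode = "multi_point"),
               "identical area grids")
})

test_that("CHAOS converts units correctly and flags degenerate input", {
  A0 <- 42.4; A <- 49.4
  ref <- stretch_curve(A0, c(A0, A), sigma = c(0, 20))
  pep <- stretch_curve(A0, c(A0, A), sigma = c(-2, 12))
  res <- sensing_free_energy(pep, ref)
  cp <- chaos_parameter(res, 0, 20)
  # ddF = -21.08 kJ/mol over delta_sigma = -20 mN/m = -12.04 kJ/mol/nm^2
  expect_equal(cp$chaos, 1.75, tolerance = 0.01)
  expect_equal(cp$chaos, res$chaos, tolerance = 1e-12)
  expect_equal(res$chaos, res$ddF / mN_m_to_kJ_mol_nm2(res$delta_sigma))
  expect_error(chaos_parameter(res, 5, 5), "zero")

  # zero sensing gives zero CHAOS
  expect_equal(chaos_parameter(sensing_free_energy(ref, ref), 0, 20)$chaos, 0)
})

test_that("CHAOS is end-state invariant for pure area-shift peptides", {
  m <- hookean_model(noise_amp = 0)
  mp <- hookean_model(dA_p = 0.5, softening = 1, noise_amp = 0)
  cur <- generate_stretch_curves(m, mp, n_frames = 10)
  prof <- chaos_invariance_profile(cur$peptide, cur$reference)
  expect_equal(prof$chaos, rep(0.5, 5), tolerance = 1e-12)
  expect_lt(attr(prof, "spread"), 1e-12)

  # with softening the profile drifts exactly per the closed form
  ms <- hookean_model(dA_p = 0.5, softening = 0.9, noise_amp = 0)
  curs <- generate_stretch_curves(m, ms, n_frames = 10)
  profs <- chaos_invariance_profile(curs$peptide, curs$reference)
  dA <- profs$area - 42.4
  expect_equal(profs$chaos, chaos_closed_form(ms, dA), tolerance = 1e-12)
  # spread across end states bounded by (1 - s) * (A_max - A0) / 2
  expect_lt(diff(range(profs$chaos)), (1 - 0.9) * 7 / 2 + 1e-12)

  # reference against itself: all zeros
  prof0 <- chaos_invariance_profile(cur$reference, cur$reference)
  expect_equal(prof0$chaos, rep(0, 5))
})

test_that("unit conversions invert to machine precision", {
  x <- c(-3.7, 0, 12.5)
  expect_equal(mN_m_to_bar_nm(bar_nm_to_mN_m(x)), x)
  expect_equal(kJ_mol_to_mN_m_nm2(mN_m_nm2_to_kJ_mol(x)), x)
  expect_equal(kJ_mol_nm2_to_mN_m(mN_m_to_kJ_mol_nm2(x)), x)
  expect_equal(bar_nm_to_mN_m(10), 1)
})
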