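test_that("XVG parsing handles legends, comments and minimal input", {
  p <- write_xvg_fixture(c("0 1.0", "10 2.0"))
  tab <- read_xvg(p)
  expect_equal(tab$time, c(0, 10))
  expect_equal(tab$col1, c(1, 2))

  p2 <- write_xvg_fixture(c("# a comment",
                            "@ s0 legend \"Pres-ZZ\"",
                            "0 1.5", "20 2.5"))
  tab2 <- read_xvg(p2)
  expect_named(tab2, c("time", "Pres-ZZ"))
  expect_equal(tab2[["Pres-ZZ"]], c(1.5, 2.5))
})

test_that("malformed XVG input is rejected with the offending line", {
  p <- write_xvg_fixture(c("0 1.0", "10 oops"))
  expect_error(read_xvg(p), "line 2")
  p2 <- write_xvg_fixture(c("0 1.0", "10 2.0 3.0"))
  expect_error(read_xvg(p2), "ragged")
  p3 <- write_xvg_fixture(c("# only comments"))
  expect_error(read_xvg(p3), "no data rows")
  expect_error(read_xvg(file.path(tempdir(), "absent.xvg")), "not found")
  p4 <- write_xvg_fixture(c("10 1.0", "10 2.0"))
  expect_error(read_xvg(p4), "strictly increasing")
})

test_that("pressure traces map default and renamed columns identically", {
  p <- make_pressure_xvg()
  tab <- read_xvg(p)
  tr <- read_pressure_trace(tab, area = 46.0)
  expect_s3_class(tr, "pressure_trace")
  expect_equal(tr$area, 46.0)
  expect_equal(tr$Lz, rep(10, 5))

  # same numbers via CSV with different headers and an explicit map
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = (0:4) * 10, P_xx_bar = -99,
                              P_yy_bar = -99, P_zz_bar = 1, height = 10),
                   csv, row.names = FALSE)
  tr2 <- read_pressure_trace(read_csv_table(csv),
                             column_map = list(Pxx = "P_xx_bar",
                                               Pyy = "P_yy_bar",
                                               Pzz = "P_zz_bar",
                                               Lz = "height"),
                             area = 46.0)
  expect_identical(surface_tension_series(tr)$sigma_mNm,
                   surface_tension_series(tr2)$sigma_mNm)
})

test_that("pressure-trace requirements are enforced", {
  tab <- read_xvg(make_pressure_xvg())
  expect_error(read_pressure_trace(tab), "area")
  expect_error(read_pressure_trace(tab, area = 46,
                                   column_map = list(area = "Box-Z")),
               "not both")
  # missing Box-Z and no constant
  p <- write_xvg_fixture(c("@ s0 legend \"Pres-XX\"",
                           "@ s1 legend \"Pres-YY\"",
                           "@ s2 legend \"Pres-ZZ\"",
                           "0 1 1 1", "10 1 1 1"))
  expect_error(read_pressure_trace(read_xvg(p), area = 46), "Box-Z")
  expect_error(pressure_trace(0:1, c(1, 1), c(1, 1), c(1, 1), Lz = -1,
                              area = 46),
               "positive")
})

test_that("case-insensitive fuzzy column matching works and is announced", {
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = (0:3) * 10, `pres.xx` = -9,
                              `pres.yy` = -9, `pres.zz` = 1, `box.z` = 10,
                              check.names = FALSE),
                   csv, row.names = FALSE)
  expect_message(tr <- read_pressure_trace(read_csv_table(csv), area = 42.4),
                 "matched")
  expect_equal(unique(tr$Pzz), 1)
})

test_that("reports round-trip through JSON and export a flat CSV schema", {
  m <- hookean_model(noise_amp = 0)
  mp <- hookean_model(dA_p = 0.5, noise_amp = 0)
  cur <- generate_stretch_curves(m, mp, n_frames = 10)
  res <- sensing_free_energy(cur$peptide, cur$reference)

  j <- withr::local_tempfile(fileext = ".json")
  write_report(res, j, "json")
  back <- read_report(j)
  expect_s3_class(back, "sensing_result")
  expect_equal(back$ddF, res$ddF)
  expect_equal(back$chaos, res$chaos)
  expect_equal(unname(unlist(back$end_states)), unname(res$end_states))

  csvp <- withr::local_tempfile(fileext = ".csv")
  write_report(res, csvp, "csv")
  tab <- utils::read.csv(csvp)
  expect_named(tab, c("name", "value", "error", "units"))
  expect_true("ddF" %in% tab$name)
  expect_equal(tab$error[tab$name == "ddF"], res$ddF_err)

  # TI result with two legs: JSON lists both legs and the sum
  spec <- cycle_spec(mp, 49.4)
  legs <- simulate_dhdl(spec, "A0")
  ti <- binding_free_energy(legs$vdw, legs$coulomb)
  j2 <- withr::local_tempfile(fileext = ".json")
  write_report(ti, j2, "json")
  ti_back <- read_report(j2)
  expect_equal(length(ti_back$dF_per_leg), 2L)
  expect_equal(sum(unlist(ti_back$dF_per_leg)), ti_back$dF_total)
})

test_that("stretch curves round-trip through the CSV schema", {
  cur <- stretch_curve(42.4, c(42.4, 45.2, 49.4), c(0, 10, 25),
                       c(0.5, 0.5, 0.6), label = "x")
  p <- withr::local_tempfile(fileext = ".csv")
  write_stretch_curve(cur, p)
  back <- read_stretch_curve(p, label = "x")
  expect_equal(back$area, cur$area)
  expect_equal(back$sigma, cur$sigma)
  expect_equal(back$sem, cur$sem)
  expect_equal(back$A0, cur$A0)
})

test_that("XVG and CSV encodings of the same run give identical tensions", {
  m <- hookean_model(noise_amp = 30)
  tr <- simulate_pressure_trace(m, 45.2, 200, seed = 11)
  xvg <- withr::local_tempfile(fileext = ".xvg")
  write_trace_xvg(tr, xvg)
  tr_x <- read_pressure_trace(read_xvg(xvg), area = 45.2)
  est_direct <- estimate_tension(tr, n_blocks = 5)
  est_xvg <- estimate_tension(tr_x, n_blocks = 5)
  expect_equal(est_xvg$sigma, est_direct$sigma, tolerance = 1e-9)
  # the precomputed engine tension column agrees with recomputation
  expect_equal(estimate_tension(tr_x, n_blocks = 5,
                                source = "surften_column")$sigma,
               est_xvg$sigma, tolerance = 1e-9)
})

test_that("FASTA round trip preserves sequences and names", {
  seqs <- c(a = "ACDW", b = "WWWW")
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, p)
  expect_equal(read_fasta_sequences(p), seqs)
})

test_that("human durations convert to ps", {
  expect_equal(parse_duration_ps("50ns"), 5e4)
  expect_equal(parse_duration_ps("100 ps"), 100)
  expect_equal(parse_duration_ps(250), 250)
  expect_error(parse_duration_ps("fifty ns"), "cannot parse")
})
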