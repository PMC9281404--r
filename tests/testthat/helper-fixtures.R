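# fixtures are built in code at test time; nothing is stored on disk

write_xvg_fixture <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".xvg", .local_envir = env)
  writeLines(lines, path)
  path
}

# a small well-formed energy-style XVG with GROMACS column names
make_pressure_xvg <- function(n = 5L, Pxx = -99, Pyy = -99, Pzz = 1,
                              Lz = 10) {
  write_xvg_fixture(c(
    "# gmx energy output",
    "@    title \"Energy\"",
    "@    xaxis  label \"Time (ps)\"",
    "@ s0 legend \"Pres-XX\"",
    "@ s1 legend \"Pres-YY\"",
    "@ s2 legend \"Pres-ZZ\"",
    "@ s3 legend \"Box-Z\"",
    sprintf("%g %g %g %g %g", (seq_len(n) - 1) * 10, Pxx, Pyy, Pzz, Lz)
  ), env = parent.frame())
}

# random but valid paired stretch curves on one grid (not Hookean)
random_curve_pair <- function() {
  A0 <- runif(1, 30, 50)
  n <- sample(3:7, 1)
  areas <- A0 + c(0, sort(runif(n - 1, 0.5, 10)))
  mk <- function(label) stretch_curve(A0, areas, sigma = rnorm(n, 0, 30),
                                      sem = runif(n, 0.1, 2), label = label)
  list(pep = mk("pep"), ref = mk("reference"))
}

toy_w_count_fitness <- function(s) {
  -vapply(strsplit(s, ""), function(a) sum(a == "W"), numeric(1))
}
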