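#' Hookean membrane + peptide model
#'
#' The generator behind every synthetic fixture: a membrane whose
#' tension is linear in area, sigma(A) = s * K_A * (A - A0 - dA_p) / A0.
#' A bound peptide perturbs the reference membrane in two ways: it
#' injects excess leaflet area `dA_p` (shifting the tensionless area)
#' and softens the elastic response by the factor `s` (modified modulus
#' K_A' = s * K_A). The reference membrane is the special case s = 1,
#' dA_p = 0. Tension fluctuations are modelled as stationary AR(1)
#' noise with amplitude `noise_amp` and correlation time `tau_corr`,
#' the simplest process that exercises block averaging nontrivially.
#'
#' Defaults emulate the coarse-grained POPC study conditions: reference
#' area 42.4 nm^2, modulus 240 mN/m, box height 11 nm, one frame per
#' 20 ps, per-frame tension scatter 60 mN/m with a 100 ps correlation
#' time.
#'
#' @param A0 tensionless reference area, nm^2.
#' @param K_A area compressibility modulus, mN/m.
#' @param dA_p peptide excess area, nm^2 (0 for no peptide).
#' @param softening elastic softening factor s in (0, 1].
#' @param noise_amp stationary tension-noise amplitude, mN/m.
#' @param tau_corr noise correlation time, ps.
#' @param Lz box height, nm.
#' @param dt frame spacing, ps.
#' @return a `hookean_model`.
#' @export
hookean_model <- function(A0 = 42.4, K_A = 240, dA_p = 0, softening = 1,
                          noise_amp = 60, tau_corr = 100, Lz = 11, dt = 20) {
  stopifnot(A0 > 0, K_A > 0, Lz > 0, dt > 0, dA_p >= 0,
            softening > 0, softening <= 1, noise_amp >= 0, tau_corr > 0)
  structure(list(A0 = A0, K_A = K_A, dA_p = dA_p, softening = softening,
                 noise_amp = noise_amp, tau_corr = tau_corr,
                 Lz = Lz, dt = dt),
            class = "hookean_model")
}

#' Model tension at a given area
#'
#' @param model a [hookean_model()].
#' @param A area, nm^2 (> 0).
#' @return tension in mN/m.
#' @export
model_tension <- function(model, A) {
  stopifnot(inherits(model, "hookean_model"), all(A > 0))
  model$softening * model$K_A * (A - model$A0 - model$dA_p) / model$A0
}

#' Closed-form sensing free energy and CHAOS of the model
#'
#' For a peptide model (s, dA_p) against the matching reference
#' membrane (same A0, K_A; s = 1, dA_p = 0), the end-state trapezoid
#' sensing free energy between A0 and A0 + dA is
#' ddF = (K_A / A0) * ((s - 1) dA^2 / 2 - s dA_p dA)   (mN/m nm^2)
#' and the CHAOS parameter is (1 - s) dA / 2 + s dA_p (nm^2), which
#' reduces to the injected excess area dA_p for a pure area-shift
#' peptide (s = 1) independently of the end state.
#'
#' @param model peptide [hookean_model()].
#' @param dA end-state area increase A - A0, nm^2.
#' @return `ddF_closed_form()`: kJ/mol; `chaos_closed_form()`: nm^2.
#' @export
ddF_closed_form <- function(model, dA) {
  s <- model$softening
  mN_m_nm2_to_kJ_mol(model$K_A / model$A0 *
                       ((s - 1) * dA^2 / 2 - s * model$dA_p * dA))
}

#' @rdname ddF_closed_form
#' @export
chaos_closed_form <- function(model, dA) {
  (1 - model$softening) * dA / 2 + model$softening * model$dA_p
}

#' Simulate a constant-area pressure trace
#'
#' Inverse problem of the tension estimator: draws a tension series
#' sigma(t) = model tension + AR(1) noise and decomposes it into
#' diagonal pressures with Pzz pinned at the 1 bar reference (only the
#' z dimension is pressure-coupled in a constant-area run) and
#' Pxx = Pyy = 1 bar - sigma(t) / Lz (bar nm over nm). Feeding the
#' result through [surface_tension_series()] recovers sigma(t) exactly.
#' The trace also carries the engine-style precomputed tension column.
#'
#' @param model a [hookean_model()].
#' @param A constant box area, nm^2.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a [pressure_trace()].
#' @export
simulate_pressure_trace <- function(model, A, n_frames, seed = NULL) {
  stopifnot(inherits(model, "hookean_model"), n_frames >= 1L)
  gen <- function() {
    mu <- model_tension(model, A)
    sig <- if (model$noise_amp == 0) {
      rep(mu, n_frames)
    } else {
      phi <- exp(-model$dt / model$tau_corr)
      e <- stats::rnorm(n_frames, sd = model$noise_amp * sqrt(1 - phi^2))
      e[1] <- stats::rnorm(1L, sd = model$noise_amp)
      mu + as.numeric(stats::filter(e, phi, method = "recursive"))
    }
    sigma_bar_nm <- mN_m_to_bar_nm(sig)
    p_lat <- 1 - sigma_bar_nm / model$Lz
    pressure_trace(time = seq_len(n_frames) * model$dt - model$dt,
                   Pxx = p_lat, Pyy = p_lat,
                   Pzz = rep(1, n_frames), Lz = model$Lz, area = A,
                   label = sprintf("synthetic A=%.3g", A),
                   surften = sigma_bar_nm)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate paired reference/peptide stretch curves
#'
#' Runs the full estimation pipeline on simulated constant-area traces
#' over a shared area grid (default: the six areas 42.4 to 49.4 nm^2 in
#' 1.4 nm^2 steps of the stretching protocol), for the peptide-free
#' reference and the peptide-bound system.
#'
#' @param model_ref reference [hookean_model()] (s = 1, dA_p = 0).
#' @param model_pep peptide [hookean_model()] (same A0 and K_A).
#' @param areas area grid, nm^2; must start at the reference A0.
#' @param n_frames frames per trace.
#' @param seed RNG seed for all traces.
#' @param n_blocks blocks for the tension error estimates.
#' @param t_discard equilibration discard, ps.
#' @return list with `reference` and `peptide` [stretch_curve()]s.
#' @export
generate_stretch_curves <- function(model_ref, model_pep,
                                    areas = seq(42.4, 49.4, by = 1.4),
                                    n_frames = 2000L, seed = NULL,
                                    n_blocks = 5L, t_discard = 0) {
  stopifnot(inherits(model_ref, "hookean_model"),
            inherits(model_pep, "hookean_model"))
  if (abs(min(areas) - model_ref$A0) > 1e-6)
    stop("area grid must start at the reference A0", call. = FALSE)
  one_curve <- function(model, label, seed_off) {
    est <- lapply(seq_along(areas), function(i) {
      tr <- simulate_pressure_trace(model, areas[i], n_frames,
                                    seed = if (is.null(seed)) NULL
                                    else seed + seed_off + i)
      estimate_tension(tr, t_discard = t_discard, n_blocks = n_blocks)
    })
    stretch_curve(model_ref$A0, areas, estimates = est, label = label)
  }
  list(reference = one_curve(model_ref, "reference", 0L),
       peptide = one_curve(model_pep, "peptide", 1000L))
}

#' Cycle-consistent TI input specification
#'
#' Couples a Hookean peptide model to an alchemical leg generator so
#' that the mechanical and alchemical estimates of the sensing free
#' energy agree by construction (the thermodynamic cycle closes). The
#' peptide-state-independent solvation baseline cancels in the sensing
#' difference, exactly as it does physically.
#'
#' @param model peptide [hookean_model()].
#' @param A_end stretched end-state area, nm^2 (> A0).
#' @param dF_solvation solvation baseline, kJ/mol.
#' @param W_bind_A0 binding work at the tensionless state, kJ/mol.
#' @param lambda_grid lambda grid spanning [0, 1].
#' @return a `cycle_spec`.
#' @export
cycle_spec <- function(model, A_end, dF_solvation = -80, W_bind_A0 = -20,
                       lambda_grid = seq(0, 1, length.out = 37L)) {
  stopifnot(inherits(model, "hookean_model"), A_end > model$A0)
  structure(list(model = model, A_end = A_end,
                 dF_solvation = dF_solvation, W_bind_A0 = W_bind_A0,
                 lambda_grid = as.numeric(lambda_grid)),
            class = "cycle_spec")
}

#' Simulate TI legs for one tension state
#'
#' Emits smooth quartic <dV/dlambda> profiles
#' f(lambda) = target + amp * (lambda^2 (1-lambda)^2 - 1/30)
#' whose shape term integrates to zero, so the two legs integrate to
#' the state's binding free energy
#' dF_b(state) = dF_solvation + W_bind(state), split 60/40 between the
#' vdW and Coulomb legs. W_bind is chosen so that
#' dF_b(A) - dF_b(A0) equals the model's closed-form mechanical sensing
#' free energy: the thermodynamic cycle closes by construction, and
#' because the shape term is identical in both states the closure is
#' exact on any shared lambda grid. Optional i.i.d. Gaussian noise of
#' standard deviation `noise` is added per lambda (and reported as the
#' per-lambda sem).
#'
#' @param spec a [cycle_spec()].
#' @param tension_state `"A0"` (tensionless) or `"A"` (stretched).
#' @param noise per-lambda Gaussian noise sd, kJ/mol.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param shape_amp named amplitudes of the zero-integral shape term.
#' @return list with `vdw` and `coulomb` [lambda_leg()]s.
#' @export
simulate_dhdl <- function(spec, tension_state = c("A0", "A"), noise = 0,
                          seed = NULL, shape_amp = c(vdw = 40, coulomb = 15)) {
  stopifnot(inherits(spec, "cycle_spec"))
  tension_state <- match.arg(tension_state)
  lam <- spec$lambda_grid
  ddF <- ddF_closed_form(spec$model, spec$A_end - spec$model$A0)
  dFb <- spec$dF_solvation + spec$W_bind_A0 +
    if (tension_state == "A") ddF else 0
  targets <- c(vdw = 0.6 * dFb, coulomb = 0.4 * dFb)
  shape <- lam^2 * (1 - lam)^2 - 1 / 30     # integrates to 0 on [0,1]
  gen <- function() {
    mk <- function(leg) {
      f <- targets[[leg]] + shape_amp[[leg]] * shape
      if (noise > 0) f <- f + stats::rnorm(length(lam), sd = noise)
      lambda_leg(leg, lam, f, dvdl_sem = noise, tension_state = tension_state)
    }
    list(vdw = mk("vdw"), coulomb = mk("coulomb"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Run one synthetic mechanical + alchemical cycle
#'
#' Convenience wrapper used by the cycle-closure checks: simulates noisy
#' stretch curves and TI legs for one peptide model, runs both pathways
#' and returns their sensing estimates plus the Welch closure report.
#'
#' @param model_pep peptide [hookean_model()].
#' @param A_end stretched end-state area, nm^2.
#' @param seed RNG seed.
#' @param n_frames frames per pressure trace.
#' @param ti_noise per-lambda noise on the TI profiles, kJ/mol.
#' @param ... passed to [cycle_spec()].
#' @return list with `mech` (`sensing_result`), `alch`, `closure`.
#' @export
synthetic_cycle <- function(model_pep, A_end = model_pep$A0 + 7,
                            seed = NULL, n_frames = 2000L, ti_noise = 1,
                            ...) {
  model_ref <- hookean_model(A0 = model_pep$A0, K_A = model_pep$K_A,
                             dA_p = 0, softening = 1,
                             noise_amp = model_pep$noise_amp,
                             tau_corr = model_pep$tau_corr,
                             Lz = model_pep$Lz, dt = model_pep$dt)
  areas <- seq(model_pep$A0, A_end, length.out = 6L)
  curves <- generate_stretch_curves(model_ref, model_pep, areas,
                                    n_frames = n_frames, seed = seed)
  mech <- sensing_free_energy(curves$peptide, curves$reference,
                              mode = "end_state")
  spec <- cycle_spec(model_pep, A_end, ...)
  legs0 <- simulate_dhdl(spec, "A0", noise = ti_noise,
                         seed = if (is.null(seed)) NULL else seed + 10000L)
  legsA <- simulate_dhdl(spec, "A", noise = ti_noise,
                         seed = if (is.null(seed)) NULL else seed + 20000L)
  ti0 <- binding_free_energy(legs0$vdw, legs0$coulomb)
  tiA <- binding_free_energy(legsA$vdw, legsA$coulomb)
  alch <- alchemical_sensing(tiA, ti0)
  closure <- cycle_closure(mech, alch,
                           n_mech = 5L,
                           n_alch = length(spec$lambda_grid))
  list(mech = mech, alch = alch, closure = closure, curves = curves)
}

#' Write a synthetic pressure trace as a GROMACS-style XVG file
#'
#' Emits the energy-file dialect ([read_xvg()] reads it back): `@`
#' legends naming the pressure components, box height and the
#' precomputed tension column.
#'
#' @param trace a [pressure_trace()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace_xvg <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  legends <- c("Pres-XX", "Pres-YY", "Pres-ZZ", "Box-Z", "#Surf*SurfTen")
  cols <- list(trace$Pxx, trace$Pyy, trace$Pzz, trace$Lz, trace$surften)
  keep <- !vapply(cols, is.null, logical(1))
  hdr <- c("# synthetic constant-area energy output",
           sprintf("# box area %.6g nm^2", trace$area),
           "@    title \"Energy\"",
           "@    xaxis  label \"Time (ps)\"",
           sprintf("@ s%d legend \"%s\"", seq_len(sum(keep)) - 1L,
                   legends[keep]))
  mat <- do.call(cbind, c(list(trace$time), cols[keep]))
  body <- apply(mat, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
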