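#' Relative area strain
#'
#' epsilon = (A - A0) / A0, the fractional box-area increase from the
#' tensionless reference area A0. The stretching protocol of the source
#' systems runs from 42.4 to 49.4 nm^2, i.e. 16.5% strain.
#'
#' @param A membrane (box) area, nm^2.
#' @param A0 tensionless reference area, nm^2 (> 0).
#' @return dimensionless strain.
#' @export
relative_strain <- function(A, A0) {
  if (!is.numeric(A0) || any(A0 <= 0))
    stop("A0 must be positive", call. = FALSE)
  (A - A0) / A0
}

#' Tension-area stretch curve
#'
#' Ordered (area, strain, tension) measurements for one system, with or
#' without a bound peptide, anchored at the tensionless reference area
#' A0 of the peptide-free membrane. Points are sorted by area; the first
#' point must sit at A0 (zero strain) and areas must be distinct.
#'
#' @param A0 tensionless reference area, nm^2.
#' @param area measurement areas, nm^2 (must include A0).
#' @param sigma tensions at `area`, mN/m; alternatively pass a list of
#'   [tension_estimate()]s via `estimates`.
#' @param sem standard errors of `sigma`, mN/m.
#' @param estimates optional list of `tension_estimate` objects used in
#'   place of `sigma`/`sem`.
#' @param label `"reference"` for the peptide-free membrane, else the
#'   peptide name.
#' @return a `stretch_curve` with fields `A0`, `area`, `strain`,
#'   `sigma`, `sem`, `label`.
#' @export
stretch_curve <- function(A0, area, sigma = NULL, sem = 0, estimates = NULL,
                          label = "") {
  stopifnot(is.numeric(A0), length(A0) == 1L, A0 > 0)
  if (!is.null(estimates)) {
    sigma <- vapply(estimates, function(e) e$sigma, numeric(1))
    sem <- vapply(estimates, function(e) e$sem, numeric(1))
  }
  n <- length(area)
  if (n < 2L) stop("a stretch curve needs at least two points", call. = FALSE)
  if (length(sem) == 1L) sem <- rep(sem, n)
  stopifnot(length(sigma) == n, length(sem) == n, all(sem >= 0), all(area > 0))
  ord <- order(area)
  area <- area[ord]; sigma <- sigma[ord]; sem <- sem[ord]
  if (any(diff(area) < 1e-9))
    stop("stretch-curve areas must be distinct", call. = FALSE)
  if (abs(area[1] - A0) > 1e-6)
    stop("first (smallest) area must equal the reference area A0",
         call. = FALSE)
  structure(list(A0 = A0, area = area,
                 strain = relative_strain(area, A0),
                 sigma = sigma, sem = sem, label = label),
            class = "stretch_curve")
}

#' @export
print.stretch_curve <- function(x, ...) {
  cat("Stretch curve", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": A0 = ", format(x$A0), " nm^2, ", length(x$area), " points, strain 0-",
      sprintf("%.1f%%", 100 * max(x$strain)), "\n", sep = "")
  print(data.frame(area_nm2 = x$area, strain = x$strain,
                   sigma_mNm = x$sigma, sem_mNm = x$sem), ...)
  invisible(x)
}

#' Fit the area compressibility modulus
#'
#' In the Hookean regime the tension is linear in strain,
#' sigma = sigma(A0) + K_A * epsilon. The fit is a weighted
#' least-squares slope of sigma against strain constrained through
#' (0, sigma(A0)); weights are 1/sem^2 when all sems are positive,
#' else uniform.
#'
#' @param curve a [stretch_curve()].
#' @return list with `K_A` (mN/m), `se` (mN/m), `sigma0` (mN/m).
#' @export
fit_area_compressibility <- function(curve) {
  stopifnot(inherits(curve, "stretch_curve"))
  eps <- curve$strain
  if (sum(eps^2) == 0)
    stop("all strains identical; cannot fit a slope", call. = FALSE)
  sigma0 <- curve$sigma[1]
  y <- curve$sigma - sigma0
  weighted <- all(curve$sem > 0)
  w <- if (weighted) 1 / curve$sem^2 else rep(1, length(eps))
  K <- sum(w * eps * y) / sum(w * eps^2)
  se <- if (weighted) {
    # slope variance plus the anchor term: the measured sigma(A0) enters
    # every residual, so its sem propagates with sensitivity
    # dK/dsigma0 = -sum(w eps) / sum(w eps^2)
    se_slope2 <- 1 / sum(w * eps^2)
    se_anchor2 <- (curve$sem[1] * sum(w * eps) / sum(w * eps^2))^2
    sqrt(se_slope2 + se_anchor2)
  } else {
    r <- y - K * eps
    n <- length(eps)
    sqrt(sum(r^2) / max(n - 1L, 1L) / sum(eps^2))
  }
  list(K_A = K, se = se, sigma0 = sigma0)
}

.sigma_sem <- function(x) {
  if (inherits(x, "tension_estimate")) c(x$sigma, x$sem)
  else c(as.numeric(x), 0)
}

#' Work of stretching between two end states
#'
#' Because tension is linear in area over the Hookean regime, the work
#' of stretching from A0 to A is the trapezoid
#' dF = (sigma(A) + sigma(A0)) / 2 * (A - A0),
#' converted to kJ/mol with 1 mN/m nm^2 = 0.6022 kJ/mol. The error is
#' the quadrature of the two tension sems.
#'
#' @param sigma_A0,sigma_A tensions at the two end states:
#'   [tension_estimate()]s or plain numbers (mN/m).
#' @param A0,A end-state areas, nm^2, A != A0.
#' @return list with `dF` (kJ/mol), `err` (kJ/mol), `dF_mNm_nm2`.
#' @export
stretch_work <- function(sigma_A0, sigma_A, A0, A) {
  if (isTRUE(all.equal(A, A0)))
    stop("end-state areas must differ", call. = FALSE)
  s0 <- .sigma_sem(sigma_A0); sA <- .sigma_sem(sigma_A)
  w_mNm <- (sA[1] + s0[1]) / 2 * (A - A0)
  err_mNm <- abs(A - A0) / 2 * sqrt(s0[2]^2 + sA[2]^2)
  list(dF = mN_m_nm2_to_kJ_mol(w_mNm), err = mN_m_nm2_to_kJ_mol(err_mNm),
       dF_mNm_nm2 = w_mNm)
}

# composite trapezoid weights for abscissae a (sorted)
.trapz_weights <- function(a) {
  n <- length(a)
  d <- diff(a)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

#' Work of stretching integrated over all curve points
#'
#' Composite trapezoid of sigma over area across every point of the
#' curve. Exact for a linear tension-area relation, where it coincides
#' with the two-point end-state [stretch_work()].
#'
#' @param curve a [stretch_curve()].
#' @return list with `dF` (kJ/mol), `err` (kJ/mol), `dF_mNm_nm2`.
#' @export
stretch_work_multipoint <- function(curve) {
  stopifnot(inherits(curve, "stretch_curve"))
  w <- .trapz_weights(curve$area)
  dF_mNm <- sum(w * curve$sigma)
  err_mNm <- sqrt(sum((w * curve$sem)^2))
  list(dF = mN_m_nm2_to_kJ_mol(dF_mNm), err = mN_m_nm2_to_kJ_mol(err_mNm),
       dF_mNm_nm2 = dF_mNm)
}

#' Sensing free energy from paired stretch curves
#'
#' The relative binding free energy of a peptide between a stretched and
#' a tensionless membrane equals the change in stretching work caused by
#' the bound peptide: ddF = dF_s' - dF_s. In `end_state` mode this is
#' evaluated directly from the four end-state tensions,
#' ddF = (A - A0)/2 * ((sigma'(A) + sigma'(A0)) - (sigma(A) + sigma(A0))),
#' in `multi_point` mode as the difference of composite-trapezoid works
#' over the full shared area grid. Negative ddF means the peptide senses
#' packing defects (it eases stretching). The result also carries the
#' peptide-free tension difference delta_sigma = sigma(A0) - sigma(A)
#' and the CHAOS parameter ddF / delta_sigma (in nm^2 after unit
#' conversion), with first-order error propagation treating the tension
#' estimates as independent.
#'
#' @param peptide_curve stretch curve with the peptide bound.
#' @param reference_curve peptide-free stretch curve on the same grid.
#' @param mode `"end_state"` (two-point trapezoid) or `"multi_point"`.
#' @return a `sensing_result` with fields `ddF`, `ddF_err` (kJ/mol),
#'   `delta_sigma` (mN/m), `chaos`, `chaos_err` (nm^2), `mode`,
#'   `end_states` (nm^2).
#' @export
sensing_free_energy <- function(peptide_curve, reference_curve,
                                mode = c("end_state", "multi_point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(peptide_curve, "stretch_curve"),
            inherits(reference_curve, "stretch_curve"))
  p <- peptide_curve; r <- reference_curve
  if (abs(p$A0 - r$A0) > 1e-6)
    stop("curves disagree on the reference area A0", call. = FALSE)
  np <- length(p$area); nr <- length(r$area)
  A0 <- r$A0
  A_end <- r$area[nr]
  if (abs(p$area[np] - A_end) > 1e-6)
    stop("curves disagree on the stretched end-state area", call. = FALSE)

  if (mode == "end_state") {
    dA <- A_end - A0
    ddF_mNm <- dA / 2 * ((p$sigma[np] + p$sigma[1]) - (r$sigma[nr] + r$sigma[1]))
    err_mNm <- abs(dA) / 2 *
      sqrt(p$sem[1]^2 + p$sem[np]^2 + r$sem[1]^2 + r$sem[nr]^2)
  } else {
    if (np != nr || any(abs(p$area - r$area) > 1e-6))
      stop("multi_point mode requires identical area grids (tolerance 1e-6 nm^2)",
           call. = FALSE)
    wp <- stretch_work_multipoint(p)
    wr <- stretch_work_multipoint(r)
    ddF_mNm <- wp$dF_mNm_nm2 - wr$dF_mNm_nm2
    err_mNm <- sqrt(kJ_mol_to_mN_m_nm2(wp$err)^2 + kJ_mol_to_mN_m_nm2(wr$err)^2)
  }

  delta_sigma <- r$sigma[1] - r$sigma[nr]          # sigma(A0) - sigma(A), mN/m
  dsig_err <- sqrt(r$sem[1]^2 + r$sem[nr]^2)
  if (abs(delta_sigma) > 0) {
    chaos <- ddF_mNm / delta_sigma                  # nm^2
    chaos_err <- .chaos_err(ddF_mNm, err_mNm, delta_sigma, dsig_err)
  } else {
    chaos <- if (ddF_mNm == 0) 0 else NA_real_
    chaos_err <- NA_real_
  }

  structure(list(ddF = mN_m_nm2_to_kJ_mol(ddF_mNm),
                 ddF_err = mN_m_nm2_to_kJ_mol(err_mNm),
                 delta_sigma = delta_sigma,
                 delta_sigma_err = dsig_err,
                 chaos = chaos, chaos_err = chaos_err,
                 mode = mode, end_states = c(A0 = A0, A = A_end),
                 peptide = p$label, reference = r$label),
            class = "sensing_result")
}

# first-order error of a ratio with independent numerator/denominator
.chaos_err <- function(num, num_err, den, den_err) {
  abs(num / den) * sqrt((num_err / num)^2 + (den_err / den)^2)
}

#' @export
print.sensing_result <- function(x, ...) {
  cat(sprintf("ddF_sensing = %.4g +/- %.3g kJ/mol  (%s, A0 = %.4g, A = %.4g nm^2)\n",
              x$ddF, x$ddF_err, x$mode, x$end_states[1], x$end_states[2]))
  cat(sprintf("delta_sigma = %.4g mN/m (peptide-free), CHAOS = %.4g +/- %.3g nm^2\n",
              x$delta_sigma, x$chaos, x$chaos_err))
  cat(if (x$ddF < 0) "=> negative ddF: the peptide senses lipid packing defects\n"
      else "=> non-negative ddF: no defect sensing\n")
  invisible(x)
}

#' Characteristic area of sensing (CHAOS)
#'
#' Normalizes the sensing free energy by the tension difference between
#' the peptide-free reference end states, CHAOS = ddF / delta_sigma with
#' delta_sigma = sigma(A0) - sigma(A). After unit conversion
#' (1 mN/m = 0.6022 kJ/mol/nm^2) the parameter has units of area per
#' molecule; it is positive for sensors (both numerator and denominator
#' negative under stretch) and independent of the chosen end states.
#'
#' @param result a `sensing_result` (its `ddF` in kJ/mol is used).
#' @param sigma_ref_A0,sigma_ref_A peptide-free [tension_estimate()]s
#'   (or numbers, mN/m) at the reference and stretched areas.
#' @return list with `chaos` (nm^2), `err`, `delta_sigma` (mN/m).
#' @export
chaos_parameter <- function(result, sigma_ref_A0, sigma_ref_A) {
  stopifnot(inherits(result, "sensing_result"))
  s0 <- .sigma_sem(sigma_ref_A0); sA <- .sigma_sem(sigma_ref_A)
  dsig <- s0[1] - sA[1]
  if (dsig == 0)
    stop("delta_sigma is zero: no stretching between the end states",
         call. = FALSE)
  dsig_kJ <- mN_m_to_kJ_mol_nm2(dsig)
  dsig_err_kJ <- mN_m_to_kJ_mol_nm2(sqrt(s0[2]^2 + sA[2]^2))
  chaos <- result$ddF / dsig_kJ
  err <- if (result$ddF == 0) abs(result$ddF_err / dsig_kJ)
  else .chaos_err(result$ddF, result$ddF_err, dsig_kJ, dsig_err_kJ)
  list(chaos = chaos, err = err, delta_sigma = dsig)
}

#' CHAOS across every choice of stretched end state
#'
#' Recomputes the end-state sensing free energy and CHAOS for each
#' non-reference area of the shared grid, i.e. end states (A0, A_i).
#' For a Hookean membrane with a pure area-shift peptide all values
#' coincide (end-state invariance); elastic softening introduces a
#' smooth, bounded drift.
#'
#' @param peptide_curve,reference_curve stretch curves on one grid.
#' @return data frame with `area`, `delta_sigma` (mN/m), `chaos`,
#'   `chaos_err` (nm^2), `ddF` (kJ/mol); the maximum relative spread
#'   (max - min) / |mean| is attached as attribute `"spread"`.
#' @export
chaos_invariance_profile <- function(peptide_curve, reference_curve) {
  p <- peptide_curve; r <- reference_curve
  stopifnot(inherits(p, "stretch_curve"), inherits(r, "stretch_curve"))
  if (length(p$area) != length(r$area) || any(abs(p$area - r$area) > 1e-6))
    stop("curves must share the area grid", call. = FALSE)
  idx <- seq_along(r$area)[-1]
  rows <- lapply(idx, function(i) {
    sub_p <- stretch_curve(p$A0, p$area[c(1, i)], p$sigma[c(1, i)],
                           p$sem[c(1, i)], label = p$label)
    sub_r <- stretch_curve(r$A0, r$area[c(1, i)], r$sigma[c(1, i)],
                           r$sem[c(1, i)], label = r$label)
    res <- sensing_free_energy(sub_p, sub_r, mode = "end_state")
    data.frame(area = r$area[i], delta_sigma = res$delta_sigma,
               chaos = res$chaos, chaos_err = res$chaos_err, ddF = res$ddF)
  })
  out <- do.call(rbind, rows)
  rng <- range(out$chaos)
  spread <- if (diff(rng) == 0) 0 else diff(rng) / abs(mean(out$chaos))
  attr(out, "spread") <- spread
  out
}

#' Discrepancy between end-state and multi-point integration
#'
#' The end-state and all-point trapezoid estimates of the sensing free
#' energy are both linear functionals of the same measured tensions, so
#' their difference has an exactly propagated standard error in which
#' the shared end-point contributions cancel. Useful to check that the
#' two integration modes agree within noise, as they must when the
#' underlying tension-area relation is linear.
#'
#' @param peptide_curve,reference_curve stretch curves on one grid.
#' @return list with `diff` (kJ/mol, multi_point - end_state), `sem`
#'   (kJ/mol) and `n_sigma` (|diff| / sem; 0 when sem is 0).
#' @export
endstate_multipoint_discrepancy <- function(peptide_curve, reference_curve) {
  p <- peptide_curve; r <- reference_curve
  if (length(p$area) != length(r$area) || any(abs(p$area - r$area) > 1e-6))
    stop("curves must share the area grid", call. = FALSE)
  n <- length(r$area)
  w <- .trapz_weights(r$area)
  e <- numeric(n)
  e[c(1, n)] <- (r$area[n] - r$area[1]) / 2
  cw <- w - e                                 # weight difference per point
  diff_mNm <- sum(cw * (p$sigma - r$sigma))
  sem_mNm <- sqrt(sum(cw^2 * (p$sem^2 + r$sem^2)))
  d <- mN_m_nm2_to_kJ_mol(diff_mNm)
  s <- mN_m_nm2_to_kJ_mol(sem_mNm)
  list(diff = d, sem = s, n_sigma = if (s > 0) abs(d) / s else 0)
}
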