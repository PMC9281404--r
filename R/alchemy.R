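#' One leg of a thermodynamic-integration calculation
#'
#' A lambda grid spanning [0, 1] with the ensemble-averaged potential
#' derivative <dV/dlambda> and its standard error at each state, for one
#' interaction class (van der Waals or Coulomb decoupling) and one
#' tension state of the membrane (tensionless `"A0"` or stretched
#' `"A"`). The profiles are oriented so that the lambda integral of a
#' leg contributes directly to the binding free energy of that state
#' (negative when binding is favourable).
#'
#' @param leg `"vdw"` or `"coulomb"`.
#' @param lambdas strictly increasing coupling parameter values
#'   including both endpoints 0 and 1.
#' @param dvdl_mean mean <dV/dlambda> per lambda, kJ/mol.
#' @param dvdl_sem standard errors, kJ/mol (>= 0; scalar recycled).
#' @param tension_state `"A0"` or `"A"`.
#' @return a `lambda_leg`.
#' @export
lambda_leg <- function(leg = c("vdw", "coulomb"), lambdas, dvdl_mean,
                       dvdl_sem = 0, tension_state = c("A0", "A")) {
  leg <- match.arg(leg)
  tension_state <- match.arg(tension_state)
  n <- length(lambdas)
  if (length(dvdl_sem) == 1L) dvdl_sem <- rep(dvdl_sem, n)
  stopifnot(length(dvdl_mean) == n, length(dvdl_sem) == n)
  if (any(lambdas < 0 | lambdas > 1))
    stop("lambda values must lie in [0, 1]", call. = FALSE)
  if (n < 2L || any(diff(lambdas) <= 0))
    stop("lambda grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (abs(lambdas[1]) > 1e-12 || abs(lambdas[n] - 1) > 1e-12)
    stop("lambda grid must include the endpoints 0 and 1", call. = FALSE)
  if (any(dvdl_sem < 0)) stop("sems must be >= 0", call. = FALSE)
  structure(list(leg = leg, lambdas = as.numeric(lambdas),
                 dvdl_mean = as.numeric(dvdl_mean),
                 dvdl_sem = as.numeric(dvdl_sem),
                 tension_state = tension_state),
            class = "lambda_leg")
}

#' Integrate one TI leg over lambda
#'
#' Numerical integral of <dV/dlambda> over [0, 1], by composite
#' trapezoid (default; exact for affine profiles) or composite Simpson
#' (uniform grid with an odd number of points; exact for quadratics).
#' The error is the quadrature of the per-lambda sems with the
#' integration weights. A smoothness diagnostic (maximum absolute
#' second difference of the profile) is reported, since a smooth
#' profile is a prerequisite for trustworthy numerical integration.
#'
#' @param leg a [lambda_leg()].
#' @param method `"trapezoid"` or `"simpson"`.
#' @return list with `dF` (kJ/mol), `err`, `method`, `smoothness`.
#' @export
ti_integrate <- function(leg, method = c("trapezoid", "simpson")) {
  stopifnot(inherits(leg, "lambda_leg"))
  method <- match.arg(method)
  lam <- leg$lambdas; f <- leg$dvdl_mean
  n <- length(lam)
  if (method == "simpson") {
    h <- diff(lam)
    if (n < 3L || n %% 2L == 0L || diff(range(h)) > 1e-9 * mean(h))
      stop("Simpson integration needs a uniform grid with an odd number of points",
           call. = FALSE)
    w <- rep(c(4, 2), length.out = n - 2L)
    w <- c(1, w[-(n - 2L)], 4, 1) # 1,4,2,...,4,1
    w <- h[1] / 3 * w
  } else {
    w <- .trapz_weights(lam)
  }
  smooth <- if (n >= 3L) max(abs(diff(f, differences = 2L))) else 0
  list(dF = sum(w * f), err = sqrt(sum((w * leg$dvdl_sem)^2)),
       method = method, smoothness = smooth)
}

#' Binding free energy from the vdW and Coulomb legs
#'
#' Sums the lambda integrals of the two decoupling legs of one tension
#' state into the binding free energy of that state.
#'
#' @param vdw,coulomb [lambda_leg()]s sharing a tension state.
#' @param method integration rule passed to [ti_integrate()].
#' @return a `ti_result` with `dF_per_leg`, `dF_total`, `dF_err`
#'   (kJ/mol), `n_lambdas`, `tension_state`.
#' @export
binding_free_energy <- function(vdw, coulomb, method = "trapezoid") {
  stopifnot(inherits(vdw, "lambda_leg"), inherits(coulomb, "lambda_leg"))
  if (vdw$tension_state != coulomb$tension_state)
    stop("legs belong to different tension states (",
         vdw$tension_state, " vs ", coulomb$tension_state, ")", call. = FALSE)
  iv <- ti_integrate(vdw, method)
  ic <- ti_integrate(coulomb, method)
  per_leg <- c(vdw = iv$dF, coulomb = ic$dF)
  structure(list(dF_per_leg = per_leg,
                 dF_total = sum(per_leg),
                 dF_err = sqrt(iv$err^2 + ic$err^2),
                 n_lambdas = length(vdw$lambdas) + length(coulomb$lambdas),
                 tension_state = vdw$tension_state,
                 method = method),
            class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("TI (%s, state %s): dF = %.4g +/- %.3g kJ/mol  (vdw %.4g, coulomb %.4g; %d lambdas)\n",
              x$method, x$tension_state, x$dF_total, x$dF_err,
              x$dF_per_leg[["vdw"]], x$dF_per_leg[["coulomb"]], x$n_lambdas))
  invisible(x)
}

#' Alchemical sensing free energy
#'
#' Difference of the binding free energies toward the stretched
#' (defect-rich) and tensionless membranes,
#' ddF_sensing = dF_b' - dF_b, with errors in quadrature. The tension
#' states recorded on the two results guard against swapped arguments.
#'
#' @param dFb_prime `ti_result` for the stretched state (`"A"`).
#' @param dFb `ti_result` for the tensionless state (`"A0"`).
#' @return list with `ddF` (kJ/mol) and `err`.
#' @export
alchemical_sensing <- function(dFb_prime, dFb) {
  stopifnot(inherits(dFb_prime, "ti_result"), inherits(dFb, "ti_result"))
  if (dFb_prime$tension_state != "A" || dFb$tension_state != "A0")
    stop("expected dFb_prime from the stretched state (A) and dFb from ",
         "the tensionless state (A0); got ", dFb_prime$tension_state,
         " and ", dFb$tension_state, call. = FALSE)
  list(ddF = dFb_prime$dF_total - dFb$dF_total,
       err = sqrt(dFb_prime$dF_err^2 + dFb$dF_err^2))
}

#' Thermodynamic-cycle closure check
#'
#' Compares the mechanical and alchemical estimates of the sensing free
#' energy, which target the same quantity by the path independence of
#' free energy. Agreement is judged with the two-tailed Welch's t test
#' (unequal variances, Welch-Satterthwaite degrees of freedom); the
#' cycle is reported as closed when p > 0.05. With zero variance the
#' test is undefined: a zero difference closes trivially, a nonzero one
#' is reported as not closed with `p = NA`.
#'
#' @param mech a `sensing_result` (mechanical pathway).
#' @param alch list with `ddF` and `err` from [alchemical_sensing()].
#' @param n_mech,n_alch replicate counts behind the two error bars
#'   (>= 2), used for the degrees of freedom.
#' @return list with `difference`, `combined_err`, `t`, `df`, `p`,
#'   `closed`.
#' @export
cycle_closure <- function(mech, alch, n_mech, n_alch) {
  stopifnot(inherits(mech, "sensing_result"),
            is.list(alch), !is.null(alch$ddF), !is.null(alch$err))
  if (n_mech < 2L || n_alch < 2L)
    stop("replicate counts must be >= 2 for Welch's t", call. = FALSE)
  d <- mech$ddF - alch$ddF
  se1 <- mech$ddF_err; se2 <- alch$err
  comb <- sqrt(se1^2 + se2^2)
  if (comb == 0) {
    closed <- d == 0
    return(list(difference = d, combined_err = 0, t = if (d == 0) 0 else Inf,
                df = NA_real_, p = NA_real_, closed = closed))
  }
  t <- d / comb
  df <- comb^4 / (se1^4 / (n_mech - 1) + se2^4 / (n_alch - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(difference = d, combined_err = comb, t = t, df = df, p = p,
       closed = p > 0.05)
}
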