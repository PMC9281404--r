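#' Curvature/radius and strain/vesicle-size mappings
#'
#' Small geometric identities linking the flat stretched-membrane
#' protocol to the curved geometries it emulates: a cylindrical buckle
#' of curvature kappa corresponds to a tube of radius R = 1/kappa; a
#' vesicle curved in two dimensions has half the mean curvature of a
#' cylinder with the same principal curvature; and the outer-leaflet
#' strain of a thin-shell vesicle of radius R with a leaflet neutral
#' plane offset d from the midplane is epsilon = 2 d / R.
#'
#' @param kappa curvature, 1/nm (positive for the radius mapping).
#' @param kappa_cyl cylindrical (one-dimensional) curvature, 1/nm.
#' @return nm or 1/nm as appropriate.
#' @examples
#' curvature_to_radius(0.08)          # 12.5 nm
#' cylindrical_to_mean_curvature(0.11) # 0.055 1/nm
#' strain_to_vesicle_radius(0.165)     # ~12.5 nm (25 nm vesicle)
#' @name geometry-maps
NULL

#' @rdname geometry-maps
#' @export
curvature_to_radius <- function(kappa) {
  if (any(kappa <= 0)) stop("curvature must be positive", call. = FALSE)
  1 / kappa
}

#' @rdname geometry-maps
#' @export
radius_to_curvature <- function(R) {
  if (any(R <= 0)) stop("radius must be positive", call. = FALSE)
  1 / R
}

#' @rdname geometry-maps
#' @export
cylindrical_to_mean_curvature <- function(kappa_cyl) kappa_cyl / 2

#' Equivalent vesicle radius of a given leaflet strain
#'
#' Thin-shell elastic mapping epsilon = 2 d / R between the relative
#' outer-leaflet strain of a vesicle and its radius, with d the
#' midplane-to-neutral-plane offset of one leaflet. The default
#' d = 1.03 nm reproduces the 25 nm-diameter vesicle corresponding to
#' 16.5% strain and is a model choice, configurable per lipid.
#'
#' @param epsilon relative strain (> 0).
#' @param R vesicle radius, nm (> 0).
#' @param d_offset leaflet neutral-plane offset, nm (> 0).
#' @return radius in nm (or strain for the inverse).
#' @export
strain_to_vesicle_radius <- function(epsilon, d_offset = 1.03) {
  if (any(epsilon <= 0))
    stop("a flat membrane (epsilon <= 0) has no finite equivalent vesicle",
         call. = FALSE)
  if (d_offset <= 0) stop("d_offset must be positive", call. = FALSE)
  2 * d_offset / epsilon
}

#' @rdname strain_to_vesicle_radius
#' @export
vesicle_radius_to_strain <- function(R, d_offset = 1.03) {
  if (any(R <= 0)) stop("radius must be positive", call. = FALSE)
  if (d_offset <= 0) stop("d_offset must be positive", call. = FALSE)
  2 * d_offset / R
}

#' Neutral-plane height profile of a buckled membrane
#'
#' @param x positions along the buckle, nm, strictly increasing within
#'   one periodic cell.
#' @param z neutral-plane heights, nm.
#' @param periodic whether the profile wraps around a periodic cell.
#' @param L cell length for the periodic case, nm; defaults to the data
#'   span plus one mean spacing.
#' @return a `buckle_plane`.
#' @export
buckle_plane <- function(x, z, periodic = TRUE, L = NULL) {
  stopifnot(length(x) == length(z))
  if (length(x) < 8L)
    stop("a buckle profile needs at least 8 points", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("x must be strictly increasing within one period", call. = FALSE)
  if (is.null(L)) L <- diff(range(x)) + mean(diff(x))
  if (periodic && L <= diff(range(x)))
    stop("periodic cell length L must exceed the data span", call. = FALSE)
  structure(list(x = as.numeric(x), z = as.numeric(z),
                 periodic = isTRUE(periodic), L = L),
            class = "buckle_plane")
}

#' Signed curvature profile of a buckled neutral plane
#'
#' Computes the plane-curve curvature kappa(x) = -z'' / (1 + z'^2)^(3/2)
#' so that a crest - a bulge toward the peptide-bearing upper leaflet -
#' is positive. Derivatives come from a smoothing-spline fit
#' ([stats::smooth.spline]); periodic profiles are handled by fitting on
#' three replicated periods and evaluating the central one. Raw second
#' differences (`method = "fd"`) are available as a cross-check; they
#' are only usable on smooth, noise-free profiles.
#'
#' @param plane a [buckle_plane()].
#' @param smoothing smoothing parameter `spar` of
#'   [stats::smooth.spline] in (0, 1]; `NULL` selects it by
#'   generalized cross-validation.
#' @param method `"spline"` (default) or `"fd"` (finite differences).
#' @return a data frame (`curvature_profile`) with `x` and `kappa`
#'   (1/nm).
#' @export
buckle_curvature_profile <- function(plane, smoothing = NULL,
                                     method = c("spline", "fd")) {
  stopifnot(inherits(plane, "buckle_plane"))
  method <- match.arg(method)
  x <- plane$x; z <- plane$z
  if (method == "spline") {
    if (plane$periodic) {
      xx <- c(x - plane$L, x, x + plane$L)
      zz <- rep(z, 3L)
    } else {
      xx <- x; zz <- z
    }
    fit <- if (is.null(smoothing)) stats::smooth.spline(xx, zz)
    else stats::smooth.spline(xx, zz, spar = smoothing)
    d1 <- stats::predict(fit, x, deriv = 1L)$y
    d2 <- stats::predict(fit, x, deriv = 2L)$y
  } else {
    d1 <- .fd_deriv(x, z, plane$periodic, plane$L)
    d2 <- .fd_deriv(x, d1, plane$periodic, plane$L)
  }
  kappa <- -d2 / (1 + d1^2)^(3 / 2)
  out <- data.frame(x = x, kappa = kappa)
  class(out) <- c("curvature_profile", "data.frame")
  out
}

# central first derivative on a (possibly nonuniform, possibly periodic)
# grid; one-sided second-order stencils at open ends
.fd_deriv <- function(x, y, periodic, L) {
  n <- length(x)
  d <- numeric(n)
  if (periodic) {
    xp <- c(x[n] - L, x, x[1] + L)
    yp <- c(y[n], y, y[1])
    d <- (yp[3:(n + 2)] - yp[1:n]) / (xp[3:(n + 2)] - xp[1:n])
  } else {
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
    d[1] <- (y[2] - y[1]) / (x[2] - x[1])
    d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  }
  d
}
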