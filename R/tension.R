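#' Per-frame surface tension from the pressure tensor
#'
#' For a membrane in the x-y plane the lateral tension follows from the
#' anisotropy of the diagonal pressure-tensor components:
#' sigma(t) = Lz(t) * (Pzz(t) - (Pxx(t) + Pyy(t)) / 2),
#' in bar nm (0.1 mN/m each). The per-frame product Lz * dP is kept
#' inside the time average: the tension is an ensemble average of a
#' mechanical observable, so the defensible estimator averages the
#' product, not the product of averages. `source = "surften_column"`
#' instead passes through a precomputed engine column (e.g. GROMACS
#' `#Surf*SurfTen`), which is definitionally the same quantity.
#'
#' @param trace a [pressure_trace()].
#' @param source `"recompute"` (default, from raw components) or
#'   `"surften_column"`.
#' @return data frame with `time` (ps), `sigma_bar_nm`, `sigma_mNm`.
#' @export
surface_tension_series <- function(trace,
                                   source = c("recompute", "surften_column")) {
  stopifnot(inherits(trace, "pressure_trace"))
  source <- match.arg(source)
  sigma_bar_nm <- if (source == "recompute") {
    trace$Lz * (trace$Pzz - (trace$Pxx + trace$Pyy) / 2)
  } else {
    if (is.null(trace$surften))
      stop("trace carries no surface-tension column; use source = \"recompute\"",
           call. = FALSE)
    trace$surften
  }
  data.frame(time = trace$time, sigma_bar_nm = sigma_bar_nm,
             sigma_mNm = bar_nm_to_mN_m(sigma_bar_nm))
}

#' Discard initial equilibration frames
#'
#' Removes frames strictly before `t_discard` (a frame exactly at the
#' cutoff is kept). Typical discards are 50 ns for coarse-grained and
#' 500 ns for atomistic production runs.
#'
#' @param x a `pressure_trace` or any data frame with a `time` column (ps).
#' @param t_discard equilibration time to drop, ps (>= 0).
#' @return same type as `x`, trimmed.
#' @export
equilibration_trim <- function(x, t_discard) {
  stopifnot(is.numeric(t_discard), length(t_discard) == 1L, t_discard >= 0)
  if (inherits(x, "pressure_trace")) {
    keep <- x$time >= t_discard
    if (!any(keep)) stop("equilibration trim removed every frame", call. = FALSE)
    out <- x
    for (f in c("time", "Pxx", "Pyy", "Pzz", "Lz", "surften"))
      if (!is.null(out[[f]])) out[[f]] <- out[[f]][keep]
    return(out)
  }
  stopifnot(is.data.frame(x), "time" %in% names(x))
  keep <- x$time >= t_discard
  if (!any(keep)) stop("equilibration trim removed every frame", call. = FALSE)
  x[keep, , drop = FALSE]
}

#' Block-averaged mean and standard error
#'
#' Splits a series into `n_blocks` contiguous equal-length blocks
#' (remainder frames dropped from the front, keeping the best-sampled
#' tail), and reports the mean of block means and the standard error
#' sd(block means, ddof = 1) / sqrt(n_blocks). With a single block the
#' sem is reported as 0. Blocking absorbs the short-range time
#' correlation of MD observables that a naive sd/sqrt(n) ignores.
#'
#' @param x numeric series.
#' @param n_blocks number of blocks (>= 1, <= length(x)).
#' @return list with `mean`, `sem`, `n_blocks`, `n_used`, `block_means`.
#' @export
block_average <- function(x, n_blocks = 5L) {
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L)
  n <- length(x)
  if (n < n_blocks)
    stop("series (", n, " frames) shorter than n_blocks = ", n_blocks,
         call. = FALSE)
  m <- n %/% n_blocks
  x <- x[(n - m * n_blocks + 1L):n]
  bm <- colMeans(matrix(x, nrow = m, ncol = n_blocks))
  sem <- if (n_blocks == 1L) 0 else stats::sd(bm) / sqrt(n_blocks)
  list(mean = mean(bm), sem = sem, n_blocks = n_blocks,
       n_used = m * n_blocks, block_means = bm)
}

#' Block-averaged tension estimate constructor
#'
#' @param sigma mean tension, mN/m.
#' @param sem standard error of the mean, mN/m (>= 0).
#' @param n_blocks,n_frames_used provenance counts.
#' @param t_discard equilibration discard used, ps.
#' @param area box area, nm^2.
#' @param label free text.
#' @return a `tension_estimate`.
#' @export
tension_estimate <- function(sigma, sem = 0, n_blocks = 1L,
                             n_frames_used = n_blocks, t_discard = 0,
                             area = NA_real_, label = "") {
  stopifnot(sem >= 0, n_blocks >= 1L, n_frames_used >= n_blocks)
  structure(list(sigma = as.numeric(sigma), sem = as.numeric(sem),
                 n_blocks = as.integer(n_blocks),
                 n_frames_used = as.integer(n_frames_used),
                 t_discard = as.numeric(t_discard),
                 area = as.numeric(area), label = label),
            class = "tension_estimate")
}

#' @export
print.tension_estimate <- function(x, ...) {
  cat(sprintf("sigma = %.4g +/- %.3g mN/m  (area %.4g nm^2, %d blocks, %d frames)\n",
              x$sigma, x$sem, x$area, x$n_blocks, x$n_frames_used))
  invisible(x)
}

#' Estimate the surface tension of one constant-area run
#'
#' Composition of [equilibration_trim()], [surface_tension_series()] and
#' [block_average()].
#'
#' @inheritParams surface_tension_series
#' @param t_discard equilibration discard, ps.
#' @param n_blocks blocks for the error estimate.
#' @return a [tension_estimate()] in mN/m.
#' @export
estimate_tension <- function(trace, t_discard = 0, n_blocks = 5L,
                             source = c("recompute", "surften_column")) {
  source <- match.arg(source)
  trimmed <- equilibration_trim(trace, t_discard)
  ser <- surface_tension_series(trimmed, source = source)
  ba <- block_average(ser$sigma_mNm, n_blocks)
  tension_estimate(sigma = ba$mean, sem = ba$sem, n_blocks = ba$n_blocks,
                   n_frames_used = ba$n_used, t_discard = t_discard,
                   area = trace$area, label = trace$label)
}

#' Replica-based tension estimate
#'
#' When several independent traces of the same system are available the
#' spread of their per-trace means gives a model-free error bar.
#'
#' @param traces list of [pressure_trace()] objects at one area.
#' @inheritParams estimate_tension
#' @return a [tension_estimate()]; `n_blocks` is the replica count.
#' @export
estimate_tension_replicas <- function(traces, t_discard = 0) {
  stopifnot(length(traces) >= 2L)
  areas <- vapply(traces, function(tr) tr$area, numeric(1))
  if (diff(range(areas)) > 1e-6)
    stop("replica traces must share the box area", call. = FALSE)
  means <- vapply(traces, function(tr) {
    ser <- surface_tension_series(equilibration_trim(tr, t_discard))
    mean(ser$sigma_mNm)
  }, numeric(1))
  k <- length(means)
  tension_estimate(sigma = mean(means), sem = stats::sd(means) / sqrt(k),
                   n_blocks = k,
                   n_frames_used = sum(vapply(traces, function(tr)
                     sum(tr$time >= t_discard), numeric(1))),
                   t_discard = t_discard, area = areas[1],
                   label = traces[[1]]$label)
}

#' Peptide-membrane binding trace
#'
#' Takes a signed peptide-to-neutral-plane distance series, applies the
#' absolute value per frame (to absorb periodic-boundary crossings)
#' first, then a centered moving average over a fixed time window
#' (default 100 ns). Only window positions that fit entirely inside the
#' trace are emitted, so a window equal to the full span yields a single
#' value, the mean |z|. The bound fraction is the fraction of raw frames
#' with |z| below `threshold`; the qualitative state is `bound` at
#' fraction >= 0.9, `partial` at >= 0.5, else `unbound` (pragmatic
#' cutoffs, configurable).
#'
#' @param time frame times, ps.
#' @param z signed peptide-neutral-plane distances, nm.
#' @param window moving-average window, ps (> 0, <= trace span).
#' @param threshold bound-state distance cutoff, nm (default 1.5, the
#'   typical initial placement distance).
#' @param cutoffs fraction-bound cutoffs for `bound` / `partial`.
#' @return list with `trace` (data frame `time`, `z_abs_avg`),
#'   `fraction_bound`, `state`, `window`, `threshold`.
#' @export
binding_trace <- function(time, z, window = 1e5, threshold = 1.5,
                          cutoffs = c(bound = 0.9, partial = 0.5)) {
  stopifnot(length(time) == length(z), window > 0)
  span <- time[length(time)] - time[1]
  if (window > span)
    stop("moving-average window (", window, " ps) exceeds the trace span (",
         span, " ps)", call. = FALSE)
  az <- abs(z)
  half <- window / 2
  eps <- 1e-9 * window
  ok <- which(time - half >= time[1] - eps & time + half <= time[length(time)] + eps)
  avg <- vapply(ok, function(i) {
    inside <- abs(time - time[i]) <= half + eps
    mean(az[inside])
  }, numeric(1))
  frac <- mean(az < threshold)
  state <- if (frac >= cutoffs[["bound"]]) "bound"
  else if (frac >= cutoffs[["partial"]]) "partial"
  else "unbound"
  list(trace = data.frame(time = time[ok], z_abs_avg = avg),
       fraction_bound = frac, state = state,
       window = window, threshold = threshold)
}
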