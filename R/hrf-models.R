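#' Sampled hemodynamic response curve
#'
#' Container for an HRF (or any impulse response) sampled on a regular time
#' grid. `amplitudes[i]` is the response at time `t0 + (i - 1) * dt` seconds.
#'
#' @param amplitudes Numeric vector of signal values (at least 2, all finite).
#' @param dt Sampling step in seconds (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `hrf_curve`.
#' @export
hrf_curve <- function(amplitudes, dt, t0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (length(amplitudes) < 2L)
    stop("an hrf_curve needs at least 2 samples")
  if (!all(is.finite(amplitudes)))
    stop("amplitudes must all be finite")
  structure(list(amplitudes = as.numeric(amplitudes), dt = dt, t0 = t0),
            class = "hrf_curve")
}

#' Sample times of an HRF curve
#' @param curve An `hrf_curve`.
#' @return Numeric vector of times in seconds.
#' @export
hrf_times <- function(curve) {
  curve$t0 + (seq_along(curve$amplitudes) - 1L) * curve$dt
}

#' @export
print.hrf_curve <- function(x, ...) {
  cat(sprintf("<hrf_curve: %d samples, dt = %.4g s, t0 = %.4g s, max = %.4g>\n",
              length(x$amplitudes), x$dt, x$t0, max(x$amplitudes)))
  invisible(x)
}

# Default shape of the canonical double-gamma response: peak delay 6 s,
# undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s
# support. These are the de facto standard defaults for event-related fMRI.
default_hrf_shape <- function() {
  list(peak_delay = 6, undershoot_delay = 16,
       peak_dispersion = 1, undershoot_dispersion = 1,
       undershoot_ratio = 6)
}

# Raw (unnormalized) double-gamma evaluated at arbitrary times (vectorized).
double_gamma_raw <- function(t, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <-
    stats::dgamma(tp, shape = shape$peak_delay / shape$peak_dispersion,
                  scale = shape$peak_dispersion) -
    stats::dgamma(tp, shape = shape$undershoot_delay / shape$undershoot_dispersion,
                  scale = shape$undershoot_dispersion) / shape$undershoot_ratio
  out
}

#' Canonical double-gamma HRF
#'
#' Difference of two gamma densities (response minus undershoot) evaluated on
#' a regular grid over `[0, duration)` and rescaled to unit maximum.
#'
#' @param dt Sampling step in seconds (> 0).
#' @param duration Support in seconds (default 32, must be >= 16).
#' @param shape_params Optional list overriding any of `peak_delay`,
#'   `undershoot_delay`, `peak_dispersion`, `undershoot_dispersion`,
#'   `undershoot_ratio`.
#' @return An `hrf_curve` with `t0 = 0` and maximum amplitude 1.
#' @export
canonical_hrf <- function(dt, duration = 32, shape_params = list()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (duration < 16) stop("`duration` must be at least 16 s")
  shape <- utils::modifyList(default_hrf_shape(), shape_params)
  t <- seq(0, duration - dt / 2, by = dt)
  h <- double_gamma_raw(t, shape)
  hrf_curve(h / max(h), dt = dt, t0 = 0)
}

#' Temporal and dispersion derivatives of the canonical HRF
#'
#' Finite-difference partial derivatives of the canonical curve: the temporal
#' derivative with respect to a small onset shift, and the dispersion
#' derivative with respect to the peak-dispersion shape parameter. Both share
#' the normalization constant of the canonical curve so that the three
#' functions form a coherent basis.
#'
#' @inheritParams canonical_hrf
#' @param time_step Onset shift in seconds for the temporal derivative
#'   (default 1, the conventional choice).
#' @param dispersion_step Step on the peak-dispersion parameter (default 0.01).
#' @return A list with elements `temporal` and `dispersion`, both `hrf_curve`s.
#' @export
hrf_derivatives <- function(dt, duration = 32, shape_params = list(),
                            time_step = 1, dispersion_step = 0.01) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (duration < 16) stop("`duration` must be at least 16 s")
  if (time_step <= 0 || dispersion_step <= 0)
    stop("derivative step sizes must be positive")
  shape <- utils::modifyList(default_hrf_shape(), shape_params)
  t <- seq(0, duration - dt / 2, by = dt)
  h <- double_gamma_raw(t, shape)
  scale <- max(h)

  h_shift <- double_gamma_raw(t - time_step, shape)
  temporal <- (h - h_shift) / time_step / scale

  shape_d <- shape
  shape_d$peak_dispersion <- shape$peak_dispersion + dispersion_step
  h_disp <- double_gamma_raw(t, shape_d)
  dispersion <- (h - h_disp) / dispersion_step / scale

  list(temporal = hrf_curve(temporal, dt = dt, t0 = 0),
       dispersion = hrf_curve(dispersion, dt = dt, t0 = 0))
}

#' Realize subject HRF parameters as a sampled curve
#'
#' Builds a curve from the ground-truth parameterization used by the
#' simulator: a double-gamma template is time-warped so that the curve's
#' measured metrics are direct functions of the parameters - the maximum
#' equals `peak_amplitude`, the argmax equals `peak_time`, and the FWHM
#' scales linearly with `width_scale`.
#'
#' @param params List with `peak_amplitude` (>= 0), `peak_time` (seconds,
#'   in `[3, 9]`), `width_scale` (> 0), `undershoot_ratio` (> 0, default 6).
#' @param dt Sampling step in seconds.
#' @param duration Support in seconds (default 32).
#' @return An `hrf_curve` with `t0 = 0`.
#' @export
subject_hrf_curve <- function(params, dt, duration = 32) {
  stopifnot(is.list(params))
  p <- utils::modifyList(list(undershoot_ratio = 6, width_scale = 1), params)
  if (is.null(p$peak_amplitude) || is.null(p$peak_time))
    stop("params must supply peak_amplitude and peak_time")
  if (!is.finite(p$width_scale) || p$width_scale <= 0)
    stop("width_scale must be positive")
  if (p$peak_amplitude < 0) stop("peak_amplitude must be non-negative")
  t <- seq(0, duration - dt / 2, by = dt)
  if (p$peak_amplitude == 0) return(hrf_curve(numeric(length(t)), dt, 0))
  shape <- default_hrf_shape()
  shape$undershoot_ratio <- p$undershoot_ratio
  # locate the template's true argmax once, to high precision
  opt <- stats::optimize(function(u) double_gamma_raw(u, shape),
                         interval = c(1, 12), maximum = TRUE, tol = 1e-9)
  t_star <- opt$maximum
  h_max <- opt$objective
  tau <- t_star + (t - p$peak_time) / p$width_scale
  amp <- p$peak_amplitude * double_gamma_raw(tau, shape) / h_max
  hrf_curve(amp, dt = dt, t0 = 0)
}

#' HRF shape metrics: peak, latency, FWHM, AUC
#'
#' `max_value` is the largest sample; `latency` the time of its first
#' occurrence; `fwhm` the distance between the linearly interpolated upward
#' and downward half-maximum crossings flanking the peak; `auc` the
#' trapezoidal integral of the curve.
#'
#' @param curve An `hrf_curve` with a positive maximum.
#' @param undefined_fwhm `"error"` (default) to fail when the curve does not
#'   cross half-maximum on both sides of the peak, or `"na"` to return
#'   `NA` for the FWHM (useful for noisy estimated curves when only peak
#'   and latency are needed).
#' @return A list of class `hrf_metrics` with `max_value`, `latency`,
#'   `fwhm`, `auc`.
#' @export
hrf_metrics <- function(curve, undefined_fwhm = c("error", "na")) {
  stopifnot(inherits(curve, "hrf_curve"))
  undefined_fwhm <- match.arg(undefined_fwhm)
  a <- curve$amplitudes
  tt <- hrf_times(curve)
  m <- max(a)
  if (m <= 0) stop("undefined metrics: curve has no positive maximum")
  i_peak <- which(a == m)[1L]
  latency <- tt[i_peak]
  half <- m / 2

  # upward crossing: last sample below half before the peak; downward
  # crossing: first sample below half after the peak
  below_l <- which(a[seq_len(i_peak)] < half)
  after <- seq.int(i_peak, length(a))
  below_r <- after[a[after] < half]
  if (length(below_l) == 0L || length(below_r) == 0L) {
    if (undefined_fwhm == "error")
      stop("undefined FWHM: curve never ",
           if (length(below_l) == 0L) "rises through half-maximum before"
           else "falls through half-maximum after", " the peak")
    fwhm <- NA_real_
  } else {
    i <- max(below_l)
    t_up <- tt[i] + curve$dt * (half - a[i]) / (a[i + 1L] - a[i])
    j <- min(below_r)
    t_dn <- tt[j - 1L] + curve$dt * (a[j - 1L] - half) / (a[j - 1L] - a[j])
    fwhm <- t_dn - t_up
  }

  auc <- sum((a[-1L] + a[-length(a)]) / 2) * curve$dt
  structure(list(max_value = m, latency = latency, fwhm = fwhm, auc = auc),
            class = "hrf_metrics")
}

#' @export
print.hrf_metrics <- function(x, ...) {
  cat(sprintf("<hrf_metrics: max %.4g, latency %.3g s, FWHM %.3g s, AUC %.4g>\n",
              x$max_value, x$latency, x$fwhm, x$auc))
  invisible(x)
}

#' Resample a curve onto a finer (microtime) grid
#'
#' Linear interpolation onto a regular grid with step `dt_target` covering
#' the same support `[t0, t_end]`; original sample values are preserved
#' wherever the grids coincide.
#'
#' @param curve An `hrf_curve`.
#' @param dt_target Target step in seconds (> 0).
#' @return An `hrf_curve` on the new grid.
#' @export
resample_to_microtime <- function(curve, dt_target) {
  stopifnot(inherits(curve, "hrf_curve"))
  if (!is.numeric(dt_target) || length(dt_target) != 1L || dt_target <= 0)
    stop("`dt_target` must be a single positive number")
  tt <- hrf_times(curve)
  t_new <- seq(curve$t0, tt[length(tt)] + dt_target * 1e-9, by = dt_target)
  amp <- stats::approx(tt, curve$amplitudes, xout = t_new, rule = 2)$y
  hrf_curve(amp, dt = dt_target, t0 = curve$t0)
}

#' Basis set for first-level GLMs
#'
#' An ordered collection of basis curves sharing one time grid, tagged with
#' its kind and the microtime settings used when the design matrix is built.
#'
#' @param curves List of `hrf_curve`s with identical `dt` and length.
#' @param kind One of `"canonical"`, `"canonical+derivatives"`, `"shrf"`,
#'   `"fir"`.
#' @param microtime_bins_per_tr Number of microtime bins per TR (default 16).
#' @param reference_bin 1-based microtime bin at which regressors are sampled
#'   within each TR (default 8, mid-acquisition).
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(curves, kind,
                      microtime_bins_per_tr = 16L, reference_bin = 8L) {
  kind <- match.arg(kind, c("canonical", "canonical+derivatives", "shrf", "fir"))
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "hrf_curve")))
  dts <- vapply(curves, `[[`, numeric(1), "dt")
  lens <- vapply(curves, function(x) length(x$amplitudes), integer(1))
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L)
    stop("all basis curves must share dt and length")
  if (kind == "canonical+derivatives" && length(curves) != 3L)
    stop("canonical+derivatives basis must have exactly 3 curves")
  if (kind == "shrf" && length(curves) != 1L)
    stop("shrf basis must have exactly 1 curve")
  if (reference_bin < 1L || reference_bin > microtime_bins_per_tr)
    stop("reference_bin must lie in [1, microtime_bins_per_tr]")
  structure(list(curves = curves, kind = kind,
                 microtime_bins_per_tr = as.integer(microtime_bins_per_tr),
                 reference_bin = as.integer(reference_bin)),
            class = "basis_set")
}

#' Canonical basis with temporal and dispersion derivatives
#'
#' Convenience constructor for the standard 3-function basis sampled at
#' microtime resolution for a given TR.
#'
#' @param tr Repetition time in seconds.
#' @param duration Basis support in seconds (default 32).
#' @param bins_per_tr Microtime bins per TR (default 16).
#' @param reference_bin Sampling bin within each TR (default 8).
#' @param include_derivatives Logical; if `FALSE` return the canonical-only
#'   basis.
#' @return A `basis_set`.
#' @export
canonical_basis <- function(tr, duration = 32, bins_per_tr = 16L,
                            reference_bin = 8L, include_derivatives = TRUE) {
  dt_m <- tr / bins_per_tr
  can <- canonical_hrf(dt_m, duration)
  if (!include_derivatives)
    return(basis_set(list(can), "canonical", bins_per_tr, reference_bin))
  d <- hrf_derivatives(dt_m, duration)
  basis_set(list(can, d$temporal, d$dispersion), "canonical+derivatives",
            bins_per_tr, reference_bin)
}

#' Serialize an HRF curve to two-column CSV
#' @param curve An `hrf_curve`.
#' @param path Output file path.
#' @export
write_hrf_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = hrf_times(curve),
                              amplitude = curve$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an HRF curve from two-column CSV
#' @param path File written by [write_hrf_csv()].
#' @return An `hrf_curve`.
#' @export
read_hrf_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(d)))
    stop("expected columns time_s and amplitude")
  dt <- diff(d$time_s)
  if (max(abs(dt - dt[1])) > 1e-6) stop("time grid is not regular")
  hrf_curve(d$amplitude, dt = dt[1], t0 = d$time_s[1])
}
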