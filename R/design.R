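#' Event design for one fMRI run
#'
#' Onsets, durations and condition labels for one run, plus the acquisition
#' geometry (TR and number of volumes). All times are in seconds from run
#' start.
#'
#' @param onsets Strictly increasing numeric vector of event onsets.
#' @param durations Non-negative numeric vector, same length as `onsets`.
#' @param conditions Character vector of condition labels per event.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes acquired.
#' @param run_id Run identifier string.
#' @return An object of class `event_design`.
#' @export
event_design <- function(onsets, durations, conditions, tr, n_volumes,
                         run_id = "run-01") {
  n <- length(onsets)
  if (length(durations) != n || length(conditions) != n)
    stop("onsets, durations and conditions must have equal length")
  if (n > 1 && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (any(durations < 0)) stop("durations must be non-negative")
  if (tr <= 0) stop("tr must be positive")
  if (n > 0 && onsets[n] + durations[n] >= tr * n_volumes)
    stop("events extend past the end of the run")
  structure(list(run_id = run_id, onsets = as.numeric(onsets),
                 durations = as.numeric(durations),
                 conditions = as.character(conditions),
                 tr = tr, n_volumes = as.integer(n_volumes)),
            class = "event_design")
}

#' @export
print.event_design <- function(x, ...) {
  cat(sprintf("<event_design %s: %d events, TR %.3g s, %d volumes (%s)>\n",
              x$run_id, length(x$onsets), x$tr, x$n_volumes,
              paste(unique(x$conditions), collapse = ", ")))
  invisible(x)
}

#' Convolve an event train with a response curve on the microtime grid
#'
#' The workhorse shared by the BOLD simulator and the design-matrix builder.
#' Zero-duration impulses (sticks) are placed at the nearest microtime bin
#' (TR / `bins_per_tr` seconds) to each onset, convolved with the curve
#' sampled on that grid, and the result is read out once per TR at the
#' reference bin. Using the same routine on both sides guarantees that the
#' generator and the model agree on the intra-TR sampling phase.
#'
#' @param design An `event_design`.
#' @param curve An `hrf_curve` (any grid; it is resampled internally).
#' @param bins_per_tr Microtime bins per TR (default 16).
#' @param reference_bin 1-based bin sampled within each TR (default 8).
#' @param onset_subset Optional logical/integer index selecting events.
#' @param amplitudes Optional per-event stick heights (default 1).
#' @return Numeric vector of length `design$n_volumes`.
#' @export
convolve_events_microtime <- function(design, curve, bins_per_tr = 16L,
                                      reference_bin = 8L,
                                      onset_subset = NULL, amplitudes = NULL) {
  stopifnot(inherits(design, "event_design"), inherits(curve, "hrf_curve"))
  onsets <- design$onsets
  if (!is.null(onset_subset)) onsets <- onsets[onset_subset]
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  if (length(amplitudes) != length(onsets))
    stop("amplitudes must match the number of selected events")
  dt_m <- design$tr / bins_per_tr
  n_m <- design$n_volumes * bins_per_tr
  u <- numeric(n_m)
  if (length(onsets) > 0) {
    idx <- round(onsets / dt_m) + 1L
    if (any(idx > n_m)) stop("event onset past the end of the run")
    for (k in seq_along(idx)) u[idx[k]] <- u[idx[k]] + amplitudes[k]
  }
  b <- if (abs(curve$dt - dt_m) < 1e-12) curve$amplitudes else
    resample_to_microtime(curve, dt_m)$amplitudes
  # shift for a curve whose first sample sits at t0 > 0 (e.g. FIR bin centers)
  lag <- round(curve$t0 / dt_m)
  full <- convolve_open(u, b)
  if (lag > 0) full <- c(numeric(lag), full)
  x_m <- full[seq_len(n_m)]
  x_m[(seq_len(design$n_volumes) - 1L) * bins_per_tr + as.integer(reference_bin)]
}

# open (linear) convolution
convolve_open <- function(x, y) stats::convolve(x, rev(y), type = "open")

#' Frame (volume acquisition) times of a design
#' @param design An `event_design`.
#' @return Numeric vector, `(0:(n_volumes-1)) * tr`.
#' @export
frame_times <- function(design) (seq_len(design$n_volumes) - 1L) * design$tr
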