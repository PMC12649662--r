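#' FIR model specification
#'
#' Deconvolution window for subject-HRF estimation: `n_bins` free amplitudes
#' spanning `window` seconds post stimulus. Defaults are 12 bins across a
#' 21 s window, i.e. a 1.75 s bin width.
#'
#' @param n_bins Number of post-stimulus bins (>= 2).
#' @param window Window length in seconds.
#' @return A list of class `fir_spec` with `n_bins`, `window`, `bin_width`.
#' @export
fir_spec <- function(n_bins = 12, window = 21) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (window <= 0) stop("window must be positive")
  structure(list(n_bins = as.integer(n_bins), window = window,
                 bin_width = window / n_bins),
            class = "fir_spec")
}

#' Build a finite impulse response design matrix
#'
#' One indicator regressor per post-stimulus bin: regressor `j` (0-based) at
#' scan time `t` counts the events whose onset satisfies
#' `j * bin_width <= t - onset < (j + 1) * bin_width`. An intercept and any
#' nuisance regressors are appended.
#'
#' @param design An `event_design`.
#' @param spec A [fir_spec()].
#' @param nuisance Optional matrix of nuisance regressors
#'   (`n_volumes` rows), e.g. outlier spike indicators.
#' @return A list of class `fir_design`: `values` (time x regressor),
#'   `names`, `fir_cols`, `spec`, `frame_times`.
#' @export
build_fir_design <- function(design, spec = fir_spec(), nuisance = NULL) {
  stopifnot(inherits(design, "event_design"), inherits(spec, "fir_spec"))
  run_secs <- design$tr * design$n_volumes
  if (spec$window > run_secs)
    stop("FIR window exceeds run duration")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != design$n_volumes)
      stop("nuisance must have n_volumes rows")
  }
  tt <- frame_times(design)
  bw <- spec$bin_width
  X <- matrix(0, design$n_volumes, spec$n_bins)
  for (onset in design$onsets) {
    lag <- tt - onset
    j <- floor(lag / bw)
    keep <- j >= 0 & j < spec$n_bins
    idx <- which(keep)
    for (i in idx) X[i, j[i] + 1L] <- X[i, j[i] + 1L] + 1
  }
  fir_names <- sprintf("fir_bin%02d", seq_len(spec$n_bins))
  vals <- cbind(X, intercept = 1)
  nms <- c(fir_names, "intercept")
  if (!is.null(nuisance)) {
    nn <- colnames(nuisance)
    if (is.null(nn)) nn <- sprintf("nuisance%02d", seq_len(ncol(nuisance)))
    vals <- cbind(vals, nuisance)
    nms <- c(nms, nn)
  }
  colnames(vals) <- nms
  structure(list(values = vals, names = nms,
                 fir_cols = seq_len(spec$n_bins), spec = spec,
                 frame_times = tt),
            class = "fir_design")
}

#' Fit the FIR GLM to every voxel of a run
#'
#' Ordinary least squares per voxel, with a joint F-test that all FIR
#' coefficients are zero (extra sum of squares against the intercept +
#' nuisance model).
#'
#' @param run A `bold_run` (or any list with a voxel x time `data` matrix).
#' @param X A `fir_design` from [build_fir_design()].
#' @return A list of class `fir_fit`: `betas` (voxel x bin), `dof`,
#'   `residual_variance`, `f_stat`, `f_p`, `spec`.
#' @export
fit_fir <- function(run, X) {
  stopifnot(inherits(X, "fir_design"))
  V <- X$values
  Y <- t(run$data) # time x voxel
  if (nrow(V) != nrow(Y))
    stop("design rows must equal the run's time dimension")
  qrX <- qr(V)
  if (qrX$rank < ncol(V)) {
    bad <- colnames(V)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(V))]]
    stop("rank-deficient FIR design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta_all <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dof <- nrow(V) - ncol(V)
  rss1 <- colSums(res^2)
  # reduced model: drop the FIR block
  V0 <- V[, -X$fir_cols, drop = FALSE]
  res0 <- qr.resid(qr(V0), Y)
  rss0 <- colSums(res0^2)
  q <- length(X$fir_cols)
  sigma2 <- rss1 / dof
  f <- pmax((rss0 - rss1) / q, 0) / ifelse(sigma2 > 0, sigma2, Inf)
  f[sigma2 == 0 & rss0 == rss1] <- 0
  structure(list(betas = t(beta_all[X$fir_cols, , drop = FALSE]),
                 residual_variance = sigma2, dof = dof,
                 f_stat = f,
                 f_p = stats::pf(f, q, dof, lower.tail = FALSE),
                 spec = X$spec),
            class = "fir_fit")
}

#' Select the peak responsive voxel within a mask
#'
#' Among in-mask voxels whose FIR F-test is significant at `alpha`, returns
#' the voxel with the largest F statistic (ties broken by lowest index).
#'
#' @param fit A `fir_fit`.
#' @param mask Integer voxel indices (or logical vector) defining the
#'   inclusive mask, e.g. the occipital label set.
#' @param alpha Significance threshold for the F-test (default 0.05, the
#'   liberal threshold used for peak selection).
#' @return A single voxel index.
#' @export
select_peak_voxel <- function(fit, mask, alpha = 0.05) {
  stopifnot(inherits(fit, "fir_fit"))
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("mask is empty")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  mask <- sort(unique(as.integer(mask)))
  ok <- mask[fit$f_p[mask] < alpha]
  if (length(ok) == 0)
    stop("no in-mask voxel passes the F threshold (no-signal); ",
         "consider relaxing alpha")
  ok[which.max(fit$f_stat[ok])]
}

#' Extract the subject-specific HRF from a fitted voxel
#'
#' The voxel's FIR coefficients become the sHRF samples, one per bin, placed
#' at bin centers (`t0 = bin_width / 2`).
#'
#' @param fit A `fir_fit`.
#' @param voxel Voxel index.
#' @param spec The [fir_spec()] used for the fit (defaults to the one stored
#'   in `fit`).
#' @return An `hrf_curve` of length `n_bins`.
#' @export
extract_shrf <- function(fit, voxel, spec = fit$spec) {
  stopifnot(inherits(fit, "fir_fit"))
  if (voxel < 1 || voxel > nrow(fit$betas))
    stop("voxel index out of range")
  hrf_curve(fit$betas[voxel, ], dt = spec$bin_width, t0 = spec$bin_width / 2)
}

#' Estimate one subject's sHRF from a checkerboard run
#'
#' Convenience wrapper: builds the FIR design (with outlier-volume nuisance
#' regressors when present), fits every voxel, selects the peak voxel within
#' the occipital mask, and extracts the sHRF.
#'
#' @param run A `bold_run` from [generate_bold()] (or loaded from disk).
#' @param design The corresponding `event_design`.
#' @param spec A [fir_spec()].
#' @param mask_region Region name used as inclusive mask (default
#'   `"occipital"`).
#' @param alpha F-test threshold for peak selection.
#' @return List with `shrf` (`hrf_curve`), `voxel`, `fit`.
#' @export
estimate_shrf <- function(run, design, spec = fir_spec(),
                          mask_region = "occipital", alpha = 0.05) {
  nuis <- outlier_regressors(run$outlier_volumes, design$n_volumes)
  X <- build_fir_design(design, spec, nuisance = nuis)
  fit <- fit_fir(run, X)
  mask <- which(run$region_labels == run$regions[[mask_region]])
  voxel <- select_peak_voxel(fit, mask, alpha)
  list(shrf = extract_shrf(fit, voxel, spec), voxel = voxel, fit = fit)
}

# one indicator column per outlier volume (NULL when none)
outlier_regressors <- function(outlier_volumes, n_volumes) {
  if (length(outlier_volumes) == 0) return(NULL)
  m <- matrix(0, n_volumes, length(outlier_volumes))
  m[cbind(outlier_volumes, seq_along(outlier_volumes))] <- 1
  colnames(m) <- sprintf("outlier%02d", seq_along(outlier_volumes))
  m
}
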