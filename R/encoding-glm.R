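#' Build the first-level design matrix for the encoding task
#'
#' Condition sticks (zero-duration impulses at onsets) are placed on the
#' microtime grid, convolved with each basis curve, and sampled at the
#' reference bin of each TR. Per-run intercepts (session effects) and any
#' per-run nuisance regressors (e.g. outlier spikes) are appended. Task
#' columns are named `condition.basisK`.
#'
#' @param designs List of `event_design`s (one per run), each event labeled
#'   with its condition (e.g. `remembered` / `forgotten`).
#' @param basis A `basis_set` of kind `canonical`, `canonical+derivatives`
#'   or `shrf`.
#' @param nuisance Optional list of per-run matrices (rows = that run's
#'   volumes).
#' @return A list of class `encoding_design`: `values` (time x regressor,
#'   runs stacked), `names`, `condition_map` (condition -> column indices),
#'   `primary_cols` (condition -> first-basis column), `run_index`, `basis`.
#' @export
build_encoding_design <- function(designs, basis, nuisance = NULL) {
  if (inherits(designs, "event_design")) designs <- list(designs)
  stopifnot(inherits(basis, "basis_set"),
            all(vapply(designs, inherits, logical(1), "event_design")))
  if (!basis$kind %in% c("canonical", "canonical+derivatives", "shrf"))
    stop("basis kind must be canonical, canonical+derivatives or shrf")
  conds <- unique(unlist(lapply(designs, `[[`, "conditions")))
  if (length(conds) == 0 || any(is.na(conds)) || any(conds == ""))
    stop("all events must carry a condition label")
  n_basis <- length(basis$curves)
  n_runs <- length(designs)
  nvols <- vapply(designs, `[[`, integer(1), "n_volumes")

  task_names <- as.vector(t(outer(conds, seq_len(n_basis),
                                  function(cn, k) paste0(cn, ".basis", k))))
  blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    d <- designs[[r]]
    tb <- matrix(0, d$n_volumes, length(conds) * n_basis)
    col <- 0L
    for (cn in conds) {
      sel <- d$conditions == cn
      for (k in seq_len(n_basis)) {
        col <- col + 1L
        if (any(sel))
          tb[, col] <- convolve_events_microtime(
            d, basis$curves[[k]], basis$microtime_bins_per_tr,
            basis$reference_bin, onset_subset = sel)
      }
    }
    blocks[[r]] <- tb
  }
  task <- do.call(rbind, blocks)

  run_index <- rep(seq_len(n_runs), times = nvols)
  sess <- matrix(0, sum(nvols), n_runs)
  sess[cbind(seq_len(sum(nvols)), run_index)] <- 1
  colnames(sess) <- sprintf("run%02d", seq_len(n_runs))

  vals <- cbind(task, sess)
  nms <- c(task_names, colnames(sess))
  if (!is.null(nuisance)) {
    stopifnot(is.list(nuisance), length(nuisance) == n_runs)
    for (r in seq_len(n_runs)) {
      nu <- nuisance[[r]]
      if (is.null(nu)) next
      nu <- as.matrix(nu)
      if (nrow(nu) != nvols[r]) stop("nuisance rows must match run volumes")
      padded <- matrix(0, sum(nvols), ncol(nu))
      padded[run_index == r, ] <- nu
      cn <- colnames(nu)
      if (is.null(cn)) cn <- sprintf("nuis%02d", seq_len(ncol(nu)))
      colnames(padded) <- sprintf("run%02d_%s", r, cn)
      vals <- cbind(vals, padded)
      nms <- c(nms, colnames(padded))
    }
  }
  colnames(vals) <- nms
  cmap <- lapply(conds, function(cn)
    which(nms %in% paste0(cn, ".basis", seq_len(n_basis))))
  names(cmap) <- conds
  structure(list(values = vals, names = nms, condition_map = cmap,
                 primary_cols = vapply(cmap, `[`, integer(1), 1L),
                 run_index = run_index, basis = basis),
            class = "encoding_design")
}

#' Substitute a subject-specific HRF for the canonical basis
#'
#' Resamples the sHRF (typically 12 FIR coefficients at bin centers) onto
#' the microtime grid over the full basis support, anchoring it at zero
#' before its first sample and after its last, and rescales it to unit
#' maximum so that parameter estimates are on the same scale as the
#' canonical analysis.
#'
#' @param shrf An `hrf_curve` (e.g. from [extract_shrf()]).
#' @param tr Repetition time in seconds.
#' @param duration Basis support in seconds (default 32).
#' @param bins_per_tr,reference_bin Microtime settings (defaults 16 and 8).
#' @return A `basis_set` of kind `shrf` with a single curve on
#'   `[0, duration)` at microtime resolution.
#' @export
substitute_basis <- function(shrf, tr, duration = 32, bins_per_tr = 16L,
                             reference_bin = 8L) {
  stopifnot(inherits(shrf, "hrf_curve"))
  if (all(shrf$amplitudes == 0))
    stop("degenerate sHRF: all amplitudes are zero")
  dt_m <- tr / bins_per_tr
  knots_t <- hrf_times(shrf)
  knots_a <- shrf$amplitudes
  if (shrf$t0 > 0) { # anchor at zero before the first FIR bin center
    knots_t <- c(0, knots_t)
    knots_a <- c(0, knots_a)
  }
  t_end <- knots_t[length(knots_t)]
  if (t_end < duration - dt_m) { # decay to zero half a step past the support
    knots_t <- c(knots_t, t_end + shrf$dt / 2)
    knots_a <- c(knots_a, 0)
  }
  t_new <- seq(0, duration - dt_m / 2, by = dt_m)
  amp <- stats::approx(knots_t, knots_a, xout = t_new, yleft = 0,
                       yright = 0)$y
  m <- max(amp)
  if (m <= 0) stop("degenerate sHRF: no positive maximum after resampling")
  basis_set(list(hrf_curve(amp / m, dt = dt_m, t0 = 0)), "shrf",
            bins_per_tr, reference_bin)
}

#' Fit the first-level encoding GLM
#'
#' Ordinary least squares across all voxels, optionally preceded by AR(1)
#' prewhitening with a single autocorrelation coefficient pooled across
#' voxels (estimated from the OLS residuals, applied run-wise).
#'
#' @param run_data A `bold_run` or list of them (one per run, matching the
#'   designs the matrix was built from).
#' @param X An `encoding_design`.
#' @param whitening Logical; apply global AR(1) prewhitening (default
#'   `FALSE`).
#' @return A list of class `glm_result`: `betas` (voxel x regressor),
#'   `residual_variance`, `dof`, `xtx_inv`, `condition_map`,
#'   `primary_cols`, `ar_coefficient`.
#' @export
fit_encoding_glm <- function(run_data, X, whitening = FALSE) {
  stopifnot(inherits(X, "encoding_design"))
  if (inherits(run_data, "bold_run")) run_data <- list(run_data)
  Y <- t(do.call(cbind, lapply(run_data, `[[`, "data"))) # time x voxel
  V <- X$values
  if (nrow(V) != nrow(Y))
    stop("concatenated run length must match the design")
  fit1 <- glm_ols(V, Y)
  rho <- 0
  if (whitening) {
    res <- fit1$residuals
    num <- 0; den <- 0
    for (r in unique(X$run_index)) {
      rows <- which(X$run_index == r)
      e <- res[rows, , drop = FALSE]
      num <- num + sum(e[-1, ] * e[-nrow(e), ])
      den <- den + sum(e[-nrow(e), ]^2)
    }
    rho <- num / den
    W <- function(M) {
      out <- M
      for (r in unique(X$run_index)) {
        rows <- which(X$run_index == r)
        M_r <- M[rows, , drop = FALSE]
        out[rows[1], ] <- sqrt(1 - rho^2) * M_r[1, ]
        out[rows[-1], ] <- M_r[-1, , drop = FALSE] -
          rho * M_r[-nrow(M_r), , drop = FALSE]
      }
      out
    }
    fit1 <- glm_ols(W(V), W(Y))
  }
  structure(list(betas = fit1$betas, residual_variance = fit1$sigma2,
                 dof = fit1$dof, xtx_inv = fit1$xtx_inv,
                 condition_map = X$condition_map,
                 primary_cols = X$primary_cols,
                 names = X$names, ar_coefficient = rho),
            class = "glm_result")
}

# shared OLS core: Y time x voxel, V time x regressor
glm_ols <- function(V, Y) {
  qrX <- qr(V)
  if (qrX$rank < ncol(V)) {
    bad <- colnames(V)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(V))]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dof <- nrow(V) - ncol(V)
  R <- qr.R(qrX)
  xtx_inv <- chol2inv(R)[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  list(betas = t(beta), residuals = res, sigma2 = colSums(res^2) / dof,
       dof = dof, xtx_inv = xtx_inv)
}

#' Correct-trials-versus-baseline contrast
#'
#' The effect at each voxel is the coefficient of the remembered condition's
#' primary basis column; derivative (or other auxiliary) columns are
#' excluded. A t statistic and two-sided p value accompany each effect.
#'
#' @param result A `glm_result`.
#' @param condition Condition name (default `"remembered"`).
#' @return Data frame with per-voxel `effect`, `t`, `p`.
#' @export
contrast_correct_vs_baseline <- function(result, condition = "remembered") {
  stopifnot(inherits(result, "glm_result"))
  if (!condition %in% names(result$primary_cols))
    stop("condition not present in the fitted design: ", condition)
  j <- result$primary_cols[[condition]]
  effect <- result$betas[, j]
  se <- sqrt(result$residual_variance * result$xtx_inv[j, j])
  t <- ifelse(se > 0, effect / se, 0)
  data.frame(effect = effect, t = t,
             p = 2 * stats::pt(abs(t), result$dof, lower.tail = FALSE))
}

#' Average a voxel map within labeled regions
#'
#' Mean of voxel values within each named region. Hemisphere sub-labels
#' (region names ending in `_L` / `_R`) are averaged together: the value for
#' the base region is the mean of its two hemisphere means.
#'
#' @param map Numeric per-voxel vector (e.g. a contrast effect map).
#' @param labels Integer label per voxel.
#' @param regions Named integer map of region name -> label.
#' @return Named numeric vector, one value per (hemisphere-merged) region.
#' @export
roi_parameter_estimate <- function(map, labels, regions) {
  if (length(map) != length(labels))
    stop("map and labels must have the same length")
  per_label <- vapply(regions, function(lab) {
    idx <- labels == lab
    if (!any(idx)) stop("empty region: label ", lab)
    mean(map[idx])
  }, numeric(1))
  base <- sub("_[LR]$", "", names(per_label))
  vapply(split(per_label, base), mean, numeric(1))[unique(base)]
}

#' Detect outlier volumes from the global signal
#'
#' Volumes whose global (across-voxel) mean signal deviates from the run
#' median by more than `z_threshold` robust standard deviations
#' (1.4826 x MAD) are flagged. A constant time series yields no outliers.
#'
#' @param run A `bold_run`.
#' @param z_threshold Robust z cutoff (default 4).
#' @return Integer vector of outlier volume indices (1-based).
#' @export
detect_outlier_volumes <- function(run, z_threshold = 4) {
  if (z_threshold <= 0) stop("z_threshold must be positive")
  g <- colMeans(run$data)
  s <- stats::mad(g) # includes the 1.4826 consistency constant
  if (s == 0) return(integer(0))
  which(abs(g - stats::median(g)) / s > z_threshold)
}
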