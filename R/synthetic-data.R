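#' Configuration of the synthetic cohort generator
#'
#' Group-level parameters for the three age groups (young 20-30, middle-aged
#' 50-62, older 63-74): indicator means/SDs and prevalences, the latent
#' 3-factor structure behind the vascular-risk indicators, and memory
#' accuracy. Defaults reproduce the study conditions: prevalences and
#' continuous-indicator moments follow the published participant table, the
#' factor blocks (metabolic / physical-inactivity / diabetic-syndrome)
#' follow the published loading pattern, and the inter-factor correlations
#' fall in the reported 0.39-0.68 range.
#'
#' Age enters through the group-specific means and thresholds, not through
#' the latent factors, so the configured `factor_correlations` are exactly
#' the correlations of the generating factors.
#'
#' @param factor_correlations Numeric length-3 vector of pairwise latent
#'   factor correlations `(r12, r13, r23)`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(factor_correlations = c(0.39, 0.53, 0.68)) {
  g <- function(y, m, o) cbind(young = y, middle = m, old = o)
  structure(list(
    age_ranges = list(young = c(20, 30), middle = c(50, 62), old = c(63, 74)),
    female_prob = c(young = 10 / 19, middle = 17 / 24, old = 13 / 20),
    factor_correlations = factor_correlations,
    # continuous indicators: factor, loading, per-group mean, per-group sd
    continuous = list(
      resting_metabolism      = list(f = 1, lambda = 0.80, mean = c(1600, 1500, 1400), sd = c(200, 220, 210)),
      visceral_fat            = list(f = 1, lambda = 0.64, mean = c(6.16, 9.92, 11.32), sd = c(4.43, 4.61, 5.63)),
      abdominal_circumference = list(f = 1, lambda = 0.54, mean = c(90.84, 103.10, 103.42), sd = c(14.38, 22.08, 19.82)),
      body_fat                = list(f = 2, lambda = 0.80, mean = c(30.19, 39.57, 35.19), sd = c(9.84, 11.44, 10.00)),
      bmi                     = list(f = 2, lambda = 0.62, mean = c(25.47, 29.98, 27.76), sd = c(5.61, 7.79, 4.84)),
      physical_activity       = list(f = 2, lambda = -0.52, mean = c(3.8, 3.2, 3.0), sd = c(0.9, 1.0, 1.0)),
      gait_speed              = list(f = 2, lambda = 0.38, mean = c(2580.95, 2837.29, 3030.26), sd = c(347.53, 521.80, 776.90)),
      arterial_stiffness      = list(f = 3, lambda = 0.40, mean = c(37.05, 46.86, 53.50), sd = c(12.27, 10.11, 12.83))
    ),
    # binary indicators: factor, loading, per-group prevalence
    binary = list(
      high_cholesterol         = list(f = 3, lambda = 0.79, prev = c(0, 0.375, 0.65)),
      hypertension             = list(f = 3, lambda = 0.65, prev = c(0, 8 / 24, 0.60)),
      diabetes                 = list(f = 3, lambda = 0.59, prev = c(1 / 19, 3 / 24, 0.30)),
      family_history_diabetes  = list(f = 3, lambda = 0.50, prev = c(2 / 19, 14 / 24, 0.60))
    ),
    memory_accuracy = list(mean = c(0.5679, 0.3896, 0.3090),
                           sd = c(0.1696, 0.1403, 0.0686))
  ), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws subjects in three age groups with vascular-risk indicators produced
#' by a latent 3-factor model, age-graded prevalences and indicator means,
#' and memory accuracy declining with age. The three generating factor
#' scores are returned alongside the indicators as ground truth
#' (`factor_metabolic`, `factor_inactivity`, `factor_diabetic`).
#'
#' @param n_young,n_middle,n_old Non-negative group sizes.
#' @param seed Integer RNG seed.
#' @param config A [cohort_config()].
#' @return A data.frame with one row per subject.
#' @export
generate_cohort <- function(n_young, n_middle, n_old, seed,
                            config = cohort_config()) {
  sizes <- c(young = n_young, middle = n_middle, old = n_old)
  if (any(!is.finite(sizes)) || any(sizes < 0) || any(sizes != round(sizes)))
    stop("group sizes must be non-negative integers")
  set.seed(seed)
  n <- sum(sizes)
  group <- rep(names(sizes), times = sizes)
  out <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(max(n, 0L))),
    age_group = factor(group, levels = c("young", "middle", "old")),
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]
  if (n == 0L) {
    out$age <- numeric(0); out$sex <- character(0)
    return(out)
  }
  gi <- as.integer(out$age_group)
  rng <- do.call(rbind, config$age_ranges)[gi, , drop = FALSE]
  out$age <- stats::runif(n, rng[, 1], rng[, 2])
  out$sex <- ifelse(stats::runif(n) < config$female_prob[gi], "F", "M")

  # latent factors ~ MVN(0, Phi)
  r <- config$factor_correlations
  phi <- diag(3)
  phi[1, 2] <- phi[2, 1] <- r[1]
  phi[1, 3] <- phi[3, 1] <- r[2]
  phi[2, 3] <- phi[3, 2] <- r[3]
  f <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(phi)
  out$factor_metabolic <- f[, 1]
  out$factor_inactivity <- f[, 2]
  out$factor_diabetic <- f[, 3]

  for (nm in names(config$continuous)) {
    sp <- config$continuous[[nm]]
    z <- sp$lambda * f[, sp$f] + sqrt(1 - sp$lambda^2) * stats::rnorm(n)
    out[[nm]] <- sp$mean[gi] + sp$sd[gi] * z
  }
  out$physical_activity <- pmin(pmax(out$physical_activity, 1), 5)
  for (nm in names(config$binary)) {
    sp <- config$binary[[nm]]
    z <- sp$lambda * f[, sp$f] + sqrt(1 - sp$lambda^2) * stats::rnorm(n)
    out[[nm]] <- as.integer(z > stats::qnorm(1 - sp$prev[gi]))
  }
  out$obesity <- as.integer(out$bmi > 30)

  ma <- config$memory_accuracy
  out$memory_accuracy <- pmin(pmax(
    stats::rnorm(n, ma$mean[gi], ma$sd[gi]), 0), 1)
  rownames(out) <- NULL
  out
}

#' Default effect configuration for ground-truth HRF parameters
#'
#' `age_slope` is the change in HRF peak amplitude per year of age (default
#' -0.004, the reported cohort effect); `risk_slope` the effect of one unit
#' of the chosen risk-factor score; `age_risk_slope` an optional age-by-risk
#' modifier on amplitude. Amplitudes are floored at `amplitude_floor`.
#'
#' @param ... Overrides for any default element.
#' @return A named list.
#' @export
hrf_effect_config <- function(...) {
  cfg <- utils::modifyList(list(
    baseline_amplitude = 0.4, age_slope = -0.004,
    risk_slope = 0.17, risk_var = "factor_metabolic", age_risk_slope = 0,
    reference_age = 49, amplitude_sd = 0.15, amplitude_floor = 0.05,
    peak_time_mean = 5.5, peak_time_sd = 0.8,
    width_mean = 1, width_sd = 0.15, undershoot_ratio = 6
  ), list(...))
  bad <- !vapply(cfg[vapply(cfg, is.numeric, logical(1))],
                 function(x) all(is.finite(x)), logical(1))
  if (any(bad)) stop("non-finite effect_config values: ",
                     paste(names(bad)[bad], collapse = ", "))
  cfg
}

#' Draw ground-truth HRF parameters for a cohort
#'
#' Peak amplitude is a linear function of centered age (and optionally a
#' risk-factor score and their product) plus Gaussian noise, floored at a
#' small positive constant; peak time and width are drawn around canonical
#' values with between-subject jitter.
#'
#' @param cohort Data frame from [generate_cohort()] (needs `age`; the risk
#'   column named by `effect_config$risk_var` is used when present).
#' @param effect_config A [hrf_effect_config()].
#' @param seed Integer RNG seed.
#' @return Data frame with columns `subject_id`, `peak_amplitude`,
#'   `peak_time`, `width_scale`, `undershoot_ratio`.
#' @export
generate_true_hrf <- function(cohort, effect_config = hrf_effect_config(),
                              seed = 1) {
  cfg <- effect_config
  num <- cfg[vapply(cfg, is.numeric, logical(1))]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite values in effect_config")
  set.seed(seed)
  n <- nrow(cohort)
  age_c <- cohort$age - cfg$reference_age
  risk <- if (!is.null(cfg$risk_var) && cfg$risk_var %in% names(cohort))
    cohort[[cfg$risk_var]] else rep(0, n)
  amp <- cfg$baseline_amplitude + cfg$age_slope * age_c +
    cfg$risk_slope * risk + cfg$age_risk_slope * age_c * risk +
    stats::rnorm(n, 0, cfg$amplitude_sd)
  amp <- pmax(amp, cfg$amplitude_floor)
  pt <- pmin(pmax(stats::rnorm(n, cfg$peak_time_mean, cfg$peak_time_sd), 3), 9)
  ws <- pmax(stats::rnorm(n, cfg$width_mean, cfg$width_sd), 0.5)
  data.frame(
    subject_id = if ("subject_id" %in% names(cohort)) cohort$subject_id
                 else sprintf("sub-%03d", seq_len(n)),
    peak_amplitude = amp, peak_time = pt, width_scale = ws,
    undershoot_ratio = cfg$undershoot_ratio,
    stringsAsFactors = FALSE
  )
}

#' Generate a checkerboard (sensory) run design
#'
#' 20 events of 1 s with inter-trial intervals drawn uniformly on 8-16 s
#' (mean 12 s) at TR 1.72 s. The run length is derived from the generated
#' trial timings plus a trailing window long enough for the FIR estimation
#' window (21 s).
#'
#' @param seed Integer RNG seed.
#' @param n_events Number of checkerboard presentations (default 20).
#' @param tr Repetition time in seconds (default 1.72).
#' @param run_id Run identifier.
#' @return An `event_design` with a single condition `"checkerboard"`.
#' @export
generate_checkerboard_design <- function(seed, n_events = 20, tr = 1.72,
                                         run_id = "checkerboard-01") {
  set.seed(seed)
  duration <- 1
  itis <- stats::runif(n_events, 8, 16) # first draw = lead-in fixation
  onsets <- cumsum(c(itis[1], itis[-1] + duration))
  n_volumes <- ceiling((onsets[n_events] + duration + 21) / tr)
  event_design(onsets, rep(duration, n_events),
               rep("checkerboard", n_events), tr, n_volumes, run_id)
}

#' Generate the two-run memory-encoding design
#'
#' Two runs of 32 trials of 3 s separated by jittered fixation (1.72-17.20 s)
#' at TR 1.72 s; each run lasts 8 minutes (279 volumes, 558 across runs).
#' Each trial receives a subsequent-memory label (`remembered` /
#' `forgotten`) drawn Bernoulli with the subject's memory accuracy.
#'
#' @param seed Integer RNG seed.
#' @param memory_accuracy Probability a trial is later remembered (default 0.5).
#' @param n_runs Number of runs (default 2).
#' @return List of `event_design`s, one per run.
#' @export
generate_encoding_design <- function(seed, memory_accuracy = 0.5, n_runs = 2) {
  if (memory_accuracy < 0 || memory_accuracy > 1)
    stop("memory_accuracy must lie in [0, 1]")
  set.seed(seed)
  tr <- 1.72
  run_secs <- 480
  n_volumes <- floor(run_secs / tr) # 279
  n_trials <- 32
  dur <- 3
  lapply(seq_len(n_runs), function(r) {
    repeat {
      jit <- stats::runif(n_trials, 1.72, 17.20)
      onsets <- cumsum(c(jit[1], jit[-1] + dur))
      if (onsets[n_trials] + dur < tr * n_volumes) break
    }
    remembered <- stats::runif(n_trials) < memory_accuracy
    event_design(onsets, rep(dur, n_trials),
                 ifelse(remembered, "remembered", "forgotten"),
                 tr, n_volumes, sprintf("encoding-%02d", r))
  })
}

#' Default noise configuration for BOLD simulation
#'
#' AR(1) temporal noise, a slow sinusoidal drift, and rare global intensity
#' spikes. `sd` is the white-noise innovation SD in signal units.
#'
#' @param ... Overrides for any default element.
#' @return A named list.
#' @export
bold_noise_config <- function(...) {
  utils::modifyList(list(ar = 0.3, sd = 0.15, drift_amplitude = 0.1,
                         drift_period = 128, spike_prob = 0.01,
                         spike_magnitude = 2), list(...))
}

#' Default region specification for BOLD simulation
#'
#' Amplitude multipliers per labeled region: positive for task-positive
#' regions (occipital, MTL), negative for task-negative default-mode regions
#' (vmPFC, PCC), zero for background.
#'
#' @param n_voxels_per_region Voxels simulated per region (default 10).
#' @param multipliers Named numeric vector of region multipliers.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(n_voxels_per_region = 10,
                        multipliers = c(occipital = 1, hippocampus = 0.8,
                                        parahippocampal = 0.8, vmPFC = -0.5,
                                        PCC = -0.5, background = 0)) {
  known <- c("occipital", "hippocampus", "parahippocampal", "vmPFC", "PCC",
             "background")
  unknown <- setdiff(names(multipliers), known)
  if (length(unknown) > 0)
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  structure(list(n_voxels_per_region = n_voxels_per_region,
                 multipliers = multipliers),
            class = "region_spec")
}

#' Simulate a BOLD run from a design and subject HRF
#'
#' The event train is convolved with the subject's HRF on the microtime grid
#' and sampled at the model's reference bin within each TR (the same routine
#' the design-matrix builder uses), scaled per region; AR(1) noise, drift,
#' and global spikes are added per the noise configuration. Injected spike
#' volumes are recorded in `outlier_volumes` (1-based).
#'
#' @param design An `event_design`.
#' @param params Subject HRF parameters (one row of [generate_true_hrf()]'s
#'   output, or a list with the same fields).
#' @param regions A [region_spec()].
#' @param noise A [bold_noise_config()]; set all elements to zero for a
#'   noiseless run.
#' @param seed Integer RNG seed.
#' @param bins_per_tr,reference_bin Microtime settings (defaults 16 and 8).
#' @return An object of class `bold_run`: list with `data` (voxel x time
#'   matrix), `tr`, `region_labels` (integer per voxel), `regions` (named
#'   label map), `outlier_volumes`.
#' @export
generate_bold <- function(design, params, regions = region_spec(),
                          noise = bold_noise_config(), seed = 1,
                          bins_per_tr = 16L, reference_bin = 8L) {
  stopifnot(inherits(design, "event_design"), inherits(regions, "region_spec"))
  set.seed(seed)
  curve <- subject_hrf_curve(as.list(params)[c("peak_amplitude", "peak_time",
                                               "width_scale",
                                               "undershoot_ratio")],
                             dt = design$tr / bins_per_tr)
  resp <- convolve_events_microtime(design, curve, bins_per_tr, reference_bin)
  n_t <- design$n_volumes
  region_names <- names(regions$multipliers)
  n_per <- regions$n_voxels_per_region
  n_vox <- n_per * length(region_names)
  labels <- rep(seq_along(region_names), each = n_per)

  data <- matrix(0, n_vox, n_t)
  for (k in seq_along(region_names)) {
    rows <- which(labels == k)
    sig <- regions$multipliers[k] * resp
    data[rows, ] <- matrix(sig, length(rows), n_t, byrow = TRUE)
  }

  outliers <- integer(0)
  if (noise$sd > 0 || noise$drift_amplitude > 0 || noise$spike_prob > 0) {
    tt <- frame_times(design)
    if (noise$sd > 0) {
      innov <- matrix(stats::rnorm(n_vox * n_t, 0, noise$sd), n_vox, n_t)
      if (noise$ar != 0) {
        for (v in seq_len(n_vox))
          innov[v, ] <- stats::filter(innov[v, ], noise$ar,
                                      method = "recursive")
      }
      data <- data + innov
    }
    if (noise$drift_amplitude > 0) {
      phase <- stats::runif(n_vox, 0, 2 * pi)
      for (v in seq_len(n_vox))
        data[v, ] <- data[v, ] + noise$drift_amplitude *
          sin(2 * pi * tt / noise$drift_period + phase[v])
    }
    if (noise$spike_prob > 0) {
      outliers <- which(stats::runif(n_t) < noise$spike_prob)
      if (length(outliers) > 0)
        data[, outliers] <- data[, outliers] + noise$spike_magnitude
    }
  }
  structure(list(data = data, tr = design$tr,
                 region_labels = labels,
                 regions = stats::setNames(seq_along(region_names),
                                           region_names),
                 outlier_volumes = outliers),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run: %d voxels x %d volumes, TR %.3g s, %d regions, %d outlier volumes>\n",
              nrow(x$data), ncol(x$data), x$tr, length(x$regions),
              length(x$outlier_volumes)))
  invisible(x)
}
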