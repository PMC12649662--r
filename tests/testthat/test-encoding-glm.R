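test_that("task column counts follow the basis: 3 per condition with derivatives, 1 with sHRF", {
  ed <- generate_encoding_design(seed = 2, memory_accuracy = 0.5)
  Xc <- build_encoding_design(ed, canonical_basis(1.72))
  expect_length(unlist(Xc$condition_map), 6)
  expect_length(Xc$primary_cols, 2)
  shrf <- substitute_basis(canonical_hrf(1.72 / 16), 1.72)
  Xs <- build_encoding_design(ed, shrf)
  expect_length(unlist(Xs$condition_map), 2)
  # session effects: one intercept column per run
  expect_true(all(c("run01", "run02") %in% Xs$names))

  unlabeled <- ed
  unlabeled[[1]]$conditions[1] <- ""
  expect_error(build_encoding_design(unlabeled, shrf), "condition label")
})

test_that("a single stick samples the basis curve at the readout offsets", {
  tr <- 1.72
  onset <- 8.6 # on the microtime grid: bin 81
  d <- event_design(onset, 0, "stim", tr, 30)
  basis <- canonical_basis(tr, include_derivatives = FALSE)
  X <- build_encoding_design(list(d), basis)
  b <- basis$curves[[1]]$amplitudes
  i0 <- round(onset / (tr / 16)) + 1
  idx <- (seq_len(30) - 1) * 16 + 8 - i0 + 1
  expected <- ifelse(idx >= 1 & idx <= length(b), b[pmax(idx, 1)], 0)
  expect_equal(unname(X$values[, 1]), expected, tolerance = 1e-12)
})

test_that("microtime convolution matches a dense-grid oracle", {
  tr <- 1.72
  set.seed(12)
  onsets <- sort(runif(10, 2, 150))
  d <- event_design(onsets, rep(0, 10), rep("stim", 10), tr, 100)
  basis <- canonical_basis(tr, include_derivatives = FALSE)
  X <- build_encoding_design(list(d), basis)

  # oracle: continuous-time sum of shifted responses, evaluated directly at
  # the readout times with snapped onsets
  dt_m <- tr / 16
  t_read <- (seq_len(100) - 1) * tr + 7 * dt_m
  onset_snap <- round(onsets / dt_m) * dt_m
  bt <- hrf_times(basis$curves[[1]])
  ba <- basis$curves[[1]]$amplitudes
  oracle <- sapply(t_read, function(t) {
    lags <- t - onset_snap
    sum(approx(bt, ba, xout = lags, yleft = 0, yright = 0)$y)
  })
  expect_lt(max(abs(X$values[, 1] - oracle)), 1e-3)
})

test_that("substituting the canonical curve reproduces the canonical-only design exactly", {
  tr <- 1.72
  ed <- generate_encoding_design(seed = 3, memory_accuracy = 0.6)
  can <- canonical_basis(tr, include_derivatives = FALSE)
  sub <- substitute_basis(can$curves[[1]], tr)
  X1 <- build_encoding_design(ed, can)
  X2 <- build_encoding_design(ed, sub)
  expect_lt(max(abs(X1$values[, 1:2] - X2$values[, 1:2])), 1e-9)
})

test_that("sHRF substitution expands a 12-point FIR curve to the full microtime support", {
  tr <- 1.72
  fir_curve <- hrf_curve(c(0.05, 0.3, 0.7, 0.9, 0.75, 0.5, 0.25, 0.1,
                           -0.03, -0.06, -0.02, 0), dt = 1.75, t0 = 0.875)
  b <- substitute_basis(fir_curve, tr)
  expect_equal(b$kind, "shrf")
  curve <- b$curves[[1]]
  expect_equal(curve$dt, tr / 16)
  # same grid as the canonical basis support (32 s)
  expect_length(curve$amplitudes,
                length(canonical_hrf(tr / 16)$amplitudes))
  expect_equal(max(curve$amplitudes), 1) # unit-max convention
  expect_equal(curve$amplitudes[1], 0)   # anchored at zero
  expect_error(substitute_basis(hrf_curve(rep(0, 12), 1.75), tr),
               "degenerate")
})

test_that("noiseless GLM recovers region multipliers to 1e-6 and is run-order invariant", {
  tr <- 1.72
  p <- test_hrf_params(peak_amplitude = 0.7, peak_time = 6.5)
  ed <- generate_encoding_design(seed = 4, memory_accuracy = 0.6)
  runs <- lapply(seq_along(ed), function(r)
    generate_bold(ed[[r]], p, noise = noiseless(), seed = r))
  true_curve <- subject_hrf_curve(p, dt = tr / 16)
  scale <- max(true_curve$amplitudes)
  basis <- basis_set(list(hrf_curve(true_curve$amplitudes / scale,
                                    true_curve$dt, 0)), "shrf")
  X <- build_encoding_design(ed, basis)
  fit <- fit_encoding_glm(runs, X)
  con <- contrast_correct_vs_baseline(fit)
  mult <- region_spec()$multipliers
  for (region in names(mult)) {
    v <- which(runs[[1]]$region_labels == runs[[1]]$regions[[region]])[1]
    expect_lt(abs(con$effect[v] / scale - mult[[region]]), 1e-6)
  }
  # run-order invariance
  X_rev <- build_encoding_design(rev(ed), basis)
  fit_rev <- fit_encoding_glm(rev(runs), X_rev)
  expect_equal(contrast_correct_vs_baseline(fit_rev)$effect, con$effect,
               tolerance = 1e-9)
})

test_that("OLS residuals are orthogonal to the design", {
  ed <- generate_encoding_design(seed = 6, memory_accuracy = 0.5)
  runs <- lapply(seq_along(ed), function(r)
    generate_bold(ed[[r]], test_hrf_params(), seed = 10 + r))
  X <- build_encoding_design(ed, canonical_basis(1.72))
  fit <- fit_encoding_glm(runs, X)
  Y <- t(cbind(runs[[1]]$data, runs[[2]]$data))
  res <- Y - X$values %*% t(fit$betas)
  expect_lt(max(abs(crossprod(X$values, res))), 1e-8)
})

test_that("AR(1) prewhitening estimates the pooled autocorrelation and keeps recovery", {
  ed <- generate_encoding_design(seed = 7, memory_accuracy = 0.6)
  p <- test_hrf_params()
  runs <- lapply(seq_along(ed), function(r)
    generate_bold(ed[[r]], p,
                  noise = bold_noise_config(ar = 0.4, sd = 0.2,
                                            drift_amplitude = 0,
                                            spike_prob = 0),
                  seed = 20 + r))
  X <- build_encoding_design(ed, canonical_basis(1.72))
  fit_w <- fit_encoding_glm(runs, X, whitening = TRUE)
  expect_gt(fit_w$ar_coefficient, 0.2)
  expect_lt(fit_w$ar_coefficient, 0.6)
  con <- contrast_correct_vs_baseline(fit_w)
  occ <- which(runs[[1]]$region_labels == runs[[1]]$regions[["occipital"]])
  expect_gt(mean(con$effect[occ]), 0)
})

test_that("contrasts propagate sign and reject missing conditions", {
  ed <- generate_encoding_design(seed = 8, memory_accuracy = 0.7)
  runs <- lapply(seq_along(ed), function(r)
    generate_bold(ed[[r]], test_hrf_params(), noise = noiseless(),
                  seed = r))
  X <- build_encoding_design(ed, canonical_basis(1.72))
  fit <- fit_encoding_glm(runs, X)
  con <- contrast_correct_vs_baseline(fit)
  neg <- which(runs[[1]]$region_labels == runs[[1]]$regions[["vmPFC"]])
  expect_true(all(con$effect[neg] < 0))
  expect_error(contrast_correct_vs_baseline(fit, "imagined"), "not present")
})

test_that("ROI averaging merges hemispheres and matches direct indexing", {
  labels <- c(1, 1, 2, 2, 3)
  regions <- c(hippocampus_L = 1, hippocampus_R = 2, vmPFC = 3)
  out <- roi_parameter_estimate(c(1, 1, 3, 3, 5), labels, regions)
  expect_equal(out[["hippocampus"]], 2) # mean of L=1 and R=3
  expect_equal(out[["vmPFC"]], 5)

  set.seed(13)
  map <- rnorm(60)
  labs <- rep(1:6, each = 10)
  regs <- setNames(1:6, paste0("r", 1:6))
  got <- roi_parameter_estimate(map, labs, regs)
  for (k in 1:6) expect_equal(got[[paste0("r", k)]], mean(map[labs == k]))
  expect_error(roi_parameter_estimate(map, labs, c(empty = 9)), "empty region")
})

test_that("outlier-volume detection flags planted spikes and spares clean runs", {
  set.seed(14)
  run <- list(data = matrix(rnorm(50 * 120), 50))
  run$data[, 17] <- run$data[, 17] + 10
  expect_equal(detect_outlier_volumes(run, 4), 17L)
  run$data[, 80] <- run$data[, 80] - 12
  expect_equal(detect_outlier_volumes(run, 4), c(17L, 80L))

  false_pos <- sum(replicate(50, {
    clean <- list(data = matrix(rnorm(50 * 120), 50))
    length(detect_outlier_volumes(clean, 5)) > 0
  }))
  expect_lte(false_pos, 1)

  flat <- list(data = matrix(1, 10, 50))
  expect_equal(detect_outlier_volumes(flat, 4), integer(0))
  expect_error(detect_outlier_volumes(flat, 0), "positive")
})
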