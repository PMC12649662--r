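test_that("the FIR design has one indicator column per bin plus intercept", {
  d <- generate_checkerboard_design(seed = 1)
  X <- build_fir_design(d, fir_spec(12, 21))
  expect_equal(length(X$fir_cols), 12)
  expect_equal(ncol(X$values), 13) # + intercept
  expect_equal(X$spec$bin_width, 1.75)

  nuis <- matrix(rnorm(d$n_volumes), ncol = 1)
  X2 <- build_fir_design(d, fir_spec(), nuisance = nuis)
  expect_equal(ncol(X2$values), 14)

  short <- event_design(2, 1, "checkerboard", tr = 1, n_volumes = 10)
  expect_error(build_fir_design(short, fir_spec(12, 21)), "window")
})

test_that("a single bin-aligned event produces a shifted identity pattern", {
  tr <- 1.75
  d <- event_design(onsets = 7, durations = 0, conditions = "stim",
                    tr = tr, n_volumes = 30)
  X <- build_fir_design(d, fir_spec(12, 21))
  fir <- X$values[, X$fir_cols]
  for (j in 1:12) {
    expect_equal(sum(fir[, j]), 1)
    expect_equal(which(fir[, j] == 1), 7 / tr + j) # scan at onset + (j-1) bins
  }
})

test_that("column sums equal a brute-force occupancy count with overlapping events", {
  tr <- 1.75
  spec <- fir_spec(12, 21)
  d <- event_design(onsets = c(7, 8.75), durations = c(0, 0),
                    conditions = c("a", "a"), tr = tr, n_volumes = 40)
  X <- build_fir_design(d, spec)
  # oracle: count scan/event pairs falling in each bin directly
  tt <- frame_times(d)
  oracle <- numeric(spec$n_bins)
  for (onset in d$onsets) for (t in tt) {
    j <- floor((t - onset) / spec$bin_width)
    if (j >= 0 && j < spec$n_bins) oracle[j + 1] <- oracle[j + 1] + 1
  }
  expect_equal(unname(colSums(X$values[, X$fir_cols])), oracle)
  expect_equal(sum(oracle), 2 * spec$n_bins)
})

test_that("FIR OLS recovers known bin amplitudes exactly and is null on zero data", {
  d <- generate_checkerboard_design(seed = 5)
  X <- build_fir_design(d, fir_spec())
  h_bins <- c(0.1, 0.5, 0.9, 1, 0.8, 0.5, 0.25, 0.1, 0, -0.1, -0.05, 0)
  y <- X$values %*% c(h_bins, 0.3) # + intercept
  run <- list(data = rbind(as.vector(y), 0))
  fit <- fit_fir(run, X)
  expect_lt(max(abs(fit$betas[1, ] - h_bins)), 1e-8)
  expect_equal(unname(fit$betas[2, ]), rep(0, 12))
  expect_equal(fit$f_stat[2], 0)
  expect_equal(fit$dof, d$n_volumes - 13)

  bad <- X
  bad$values <- cbind(bad$values, intercept2 = 1)
  bad$names <- colnames(bad$values)
  expect_error(fit_fir(run, bad), "rank-deficient.*intercept")
})

test_that("FIR equals selective epoch averaging for isolated bin-aligned events", {
  tr <- 1.75
  spec <- fir_spec(12, 21)
  onsets <- c(7, 49, 91, 133) # gaps far exceed the window
  d <- event_design(onsets, rep(0, 4), rep("stim", 4), tr = tr,
                    n_volumes = 100)
  X <- build_fir_design(d, spec)
  set.seed(20)
  y <- as.vector(X$values %*% c(seq(0.1, 1.2, length.out = 12), 0.5)) +
    rnorm(100, 0, 0.1)
  fit <- fit_fir(list(data = matrix(y, 1)), X)
  # oracle: average across epochs minus the mean of unoccupied scans
  occupied <- rowSums(X$values[, X$fir_cols]) > 0
  baseline <- mean(y[!occupied])
  epoch <- sapply(1:12, function(j) {
    scans <- onsets / tr + j
    mean(y[scans]) - baseline
  })
  expect_equal(unname(fit$betas[1, ]), epoch, tolerance = 1e-10)
})

test_that("the FIR F-test holds its size on white-noise voxels", {
  d <- generate_checkerboard_design(seed = 9)
  X <- build_fir_design(d, fir_spec())
  set.seed(10)
  noise <- matrix(rnorm(2000 * d$n_volumes), 2000)
  fit <- fit_fir(list(data = noise), X)
  rate <- mean(fit$f_p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("peak-voxel selection takes the strongest supra-threshold voxel deterministically", {
  fit <- structure(list(
    betas = matrix(0, 5, 12),
    f_stat = c(1, 8, 8, 20, 3),
    f_p = c(0.5, 0.01, 0.01, 0.001, 0.2),
    dof = 100, spec = fir_spec()), class = "fir_fit")
  expect_equal(select_peak_voxel(fit, mask = 1:5, alpha = 0.05), 4)
  # tie on F within the mask: lowest index wins
  expect_equal(select_peak_voxel(fit, mask = c(2, 3), alpha = 0.05), 2)
  expect_equal(select_peak_voxel(fit, mask = c(3, 2), alpha = 0.05), 2)
  expect_error(select_peak_voxel(fit, mask = c(1, 5), alpha = 0.05),
               "no-signal")
  expect_error(select_peak_voxel(fit, mask = integer(0)), "empty")
})

test_that("a planted high-SNR voxel is selected nearly always", {
  d <- generate_checkerboard_design(seed = 13)
  spec <- fir_spec()
  X <- build_fir_design(d, spec)
  h_bins <- hrf_metrics(subject_hrf_curve(test_hrf_params(), 0.05))$max_value *
    exp(-((1:12) - 4)^2 / 4) # smooth bump
  hits <- 0
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    set.seed(100 + s)
    data <- matrix(rnorm(30 * d$n_volumes, 0, 0.5), 30)
    data[17, ] <- data[17, ] + as.vector(X$values[, 1:12] %*% h_bins)
    fit <- fit_fir(list(data = data), X)
    sel <- tryCatch(select_peak_voxel(fit, 1:30, 0.05), error = function(e) NA)
    hits <- hits + identical(sel, 17L) + identical(sel, 17)
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("sHRF extraction yields a 12-sample curve at bin centers", {
  d <- generate_checkerboard_design(seed = 21)
  p <- test_hrf_params(peak_amplitude = 0.9, peak_time = 6)
  run <- generate_bold(d, p, noise = noiseless(), seed = 1)
  est <- estimate_shrf(run, d)
  expect_length(est$shrf$amplitudes, 12)
  expect_equal(est$shrf$dt, 1.75)
  expect_equal(est$shrf$t0, 0.875)
  # noiseless recovery: latency within one bin, and the peak attenuated by
  # no more than the worst-case 1.75 s bin-averaging loss of the true curve
  m <- hrf_metrics(est$shrf)
  dense <- subject_hrf_curve(p, dt = 0.005)
  tt <- hrf_times(dense)
  bw <- 1.75
  window_avg <- sapply(seq(6 - bw, 6, by = 0.05), function(a)
    mean(dense$amplitudes[tt >= a & tt < a + bw]))
  worst_loss <- 0.9 - min(window_avg)
  expect_lt(abs(m$max_value - 0.9), worst_loss + 0.01)
  expect_gt(m$max_value, 0.9 - worst_loss - 0.01)
  expect_lt(abs(m$latency - 6), 1.75)

  expect_error(extract_shrf(est$fit, 10^6), "out of range")
  zero_fit <- est$fit
  zero_fit$betas[est$voxel, ] <- 0
  expect_error(hrf_metrics(extract_shrf(zero_fit, est$voxel)), "undefined")
})

test_that("median F increases monotonically with SNR", {
  d <- generate_checkerboard_design(seed = 30)
  X <- build_fir_design(d, fir_spec())
  h_bins <- exp(-((1:12) - 4)^2 / 4)
  med_f <- sapply(c(0.2, 0.6, 1.2), function(amp) {
    set.seed(31)
    signal <- as.vector(X$values[, 1:12] %*% (amp * h_bins))
    data <- matrix(rnorm(50 * d$n_volumes, 0, 0.5), 50, byrow = TRUE)
    data <- sweep(data, 2, signal, "+")
    median(fit_fir(list(data = data), X)$f_stat)
  })
  expect_true(all(diff(med_f) > 0))
})
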