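test_that("cohort generation respects sizes, ranges, and determinism", {
  co <- generate_cohort(19, 24, 20, seed = 1)
  expect_equal(nrow(co), 63)
  expect_equal(as.integer(table(co$age_group)), c(19, 24, 20))
  expect_true(all(co$age[co$age_group == "young"] >= 20 &
                    co$age[co$age_group == "young"] <= 30))
  expect_true(all(co$age[co$age_group == "middle"] >= 50 &
                    co$age[co$age_group == "middle"] <= 62))
  expect_true(all(co$age[co$age_group == "old"] >= 63 &
                    co$age[co$age_group == "old"] <= 74))
  binaries <- c("diabetes", "family_history_diabetes", "hypertension",
                "high_cholesterol", "obesity")
  for (b in binaries) expect_true(all(co[[b]] %in% c(0L, 1L)))
  expect_true(all(co$memory_accuracy >= 0 & co$memory_accuracy <= 1))

  expect_identical(co, generate_cohort(19, 24, 20, seed = 1))
  expect_false(identical(co, generate_cohort(19, 24, 20, seed = 2)))

  empty <- generate_cohort(0, 0, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(generate_cohort(-1, 5, 5, seed = 1), "non-negative")
})

test_that("risk prevalences increase with age as in the participant table", {
  co <- generate_cohort(300, 300, 300, seed = 3)
  prev <- function(v) tapply(v, co$age_group, mean)
  for (b in c("hypertension", "high_cholesterol", "diabetes",
              "family_history_diabetes")) {
    p <- prev(co[[b]])
    expect_lt(p["young"], p["middle"])
    expect_lte(p["middle"], p["old"] + 0.05)
  }
  # young hypertension prevalence is exactly zero, as observed
  expect_equal(sum(co$hypertension[co$age_group == "young"]), 0)
  # memory accuracy declines across groups
  ma <- prev(co$memory_accuracy)
  expect_gt(ma["young"], ma["middle"])
  expect_gt(ma["middle"], ma["old"])
})

test_that("latent factor correlations match the configuration at n = 600", {
  co <- generate_cohort(200, 200, 200, seed = 7)
  f <- as.matrix(co[, c("factor_metabolic", "factor_inactivity",
                        "factor_diabetic")])
  r <- cor(f)
  target <- cohort_config()$factor_correlations
  expect_lt(abs(r[1, 2] - target[1]), 0.1)
  expect_lt(abs(r[1, 3] - target[2]), 0.1)
  expect_lt(abs(r[2, 3] - target[3]), 0.1)
})

test_that("ground-truth HRF amplitudes follow the configured age slope", {
  co <- data.frame(subject_id = c("a", "b"), age = c(25, 70))
  cfg <- hrf_effect_config(age_slope = -0.004, amplitude_sd = 0,
                           risk_slope = 0, peak_time_sd = 0, width_sd = 0)
  tr <- generate_true_hrf(co, cfg, seed = 1)
  expect_equal(tr$peak_amplitude[1] - tr$peak_amplitude[2], 45 * 0.004)

  flat <- generate_true_hrf(co, hrf_effect_config(age_slope = 0,
                                                  amplitude_sd = 0,
                                                  risk_slope = 0,
                                                  peak_time_sd = 0,
                                                  width_sd = 0), seed = 1)
  expect_equal(flat$peak_amplitude[1], flat$peak_amplitude[2])
  expect_equal(flat$peak_time[1], flat$peak_time[2])

  t1 <- generate_true_hrf(co, seed = 9)
  t2 <- generate_true_hrf(co, seed = 9)
  expect_identical(t1, t2)
  expect_error(hrf_effect_config(age_slope = NaN), "non-finite")
})

test_that("the configured age slope is recovered by OLS on a large cohort", {
  co <- generate_cohort(200, 200, 200, seed = 11)
  tr <- generate_true_hrf(co, hrf_effect_config(risk_slope = 0), seed = 12)
  fit <- summary(lm(tr$peak_amplitude ~ co$age))
  b <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(b - (-0.004)), 2 * se)
})

test_that("checkerboard designs have 20 events with uniform 8-16 s intervals", {
  d <- generate_checkerboard_design(seed = 3)
  expect_length(d$onsets, 20)
  expect_equal(unique(d$durations), 1)
  itis <- diff(d$onsets) - 1
  expect_true(all(itis >= 8 & itis <= 16))
  expect_equal(d$tr, 1.72)
  # the run covers the last trial plus the 21 s estimation window
  expect_gte(d$tr * d$n_volumes, d$onsets[20] + 1 + 21)
  expect_identical(d, generate_checkerboard_design(seed = 3))
})

test_that("encoding designs match the acquisition arithmetic and label trials", {
  ed <- generate_encoding_design(seed = 5, memory_accuracy = 0.5)
  expect_length(ed, 2)
  expect_equal(sum(vapply(ed, `[[`, integer(1), "n_volumes")), 558)
  for (run in ed) {
    expect_length(run$onsets, 32)
    expect_equal(unique(run$durations), 3)
    jit <- c(run$onsets[1], diff(run$onsets) - 3)
    expect_true(all(jit >= 1.72 & jit <= 17.20))
    expect_lt(run$onsets[32] + 3, 480)
    expect_true(all(run$conditions %in% c("remembered", "forgotten")))
  }
  all_rem <- generate_encoding_design(seed = 5, memory_accuracy = 1)
  expect_true(all(unlist(lapply(all_rem, `[[`, "conditions")) == "remembered"))
})

test_that("a noiseless BOLD voxel equals the sampled response to its events", {
  tr <- 1.72
  onset <- 17.2 # on the microtime grid
  d <- event_design(onset, 1, "checkerboard", tr, 40)
  p <- test_hrf_params()
  run <- generate_bold(d, p, region_spec(n_voxels_per_region = 2),
                       noiseless(), seed = 1)
  # index-arithmetic oracle: stick at microtime bin round(onset/dt)+1,
  # readout at bins (k-1)*16 + 8
  curve <- subject_hrf_curve(p, dt = tr / 16)
  b <- curve$amplitudes
  i0 <- round(onset / (tr / 16)) + 1
  idx <- (seq_len(40) - 1) * 16 + 8 - i0 + 1
  expected <- ifelse(idx >= 1 & idx <= length(b), b[pmax(idx, 1)], 0)
  occ <- which(run$region_labels == run$regions[["occipital"]])[1]
  expect_equal(unname(run$data[occ, ]), expected, tolerance = 1e-12)

  # task-negative region dips below baseline shortly after the onset
  neg <- which(run$region_labels == run$regions[["vmPFC"]])[1]
  win <- which(frame_times(d) >= onset & frame_times(d) <= onset + 10)
  expect_lt(min(run$data[neg, win]), 0)
  # background voxels carry no signal
  bg <- which(run$region_labels == run$regions[["background"]])[1]
  expect_true(all(run$data[bg, ] == 0))
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  d <- event_design(numeric(0), numeric(0), character(0), tr = 1, 5000)
  run <- generate_bold(d, test_hrf_params(),
                       region_spec(n_voxels_per_region = 1),
                       bold_noise_config(ar = 0.4, sd = 1,
                                         drift_amplitude = 0,
                                         spike_prob = 0), seed = 8)
  x <- run$data[1, ]
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.4), 0.05)
})

test_that("injected spikes are recorded and unknown regions rejected", {
  d <- generate_checkerboard_design(seed = 2)
  run <- generate_bold(d, test_hrf_params(),
                       noise = bold_noise_config(spike_prob = 0.05,
                                                 spike_magnitude = 5),
                       seed = 4)
  expect_gt(length(run$outlier_volumes), 0)
  expect_true(all(run$outlier_volumes >= 1 &
                    run$outlier_volumes <= d$n_volumes))
  expect_error(region_spec(multipliers = c(thalamus = 1)), "unknown region")
})

test_that("BOLD generation is reproducible given the seed", {
  d <- generate_checkerboard_design(seed = 2)
  r1 <- generate_bold(d, test_hrf_params(), seed = 6)
  r2 <- generate_bold(d, test_hrf_params(), seed = 6)
  expect_identical(r1$data, r2$data)
})
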