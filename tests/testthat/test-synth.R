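# Synthetic EEG and cohort generation.

test_that("Rice-mean amplitude calibration is exact at the floor, monotone, and matches Monte Carlo", {
  floor_amp <- 0.12
  expect_identical(calibrate_amplitude(1, floor_amp), 0)
  expect_error(calibrate_amplitude(0.8, floor_amp), ">= 1")

  grid <- calibrate_amplitude(seq(1, 6, by = 0.25), floor_amp)
  expect_true(all(diff(grid) > 0))

  # Monte-Carlo oracle: mean of |a e^{i phi} + Z| over 1e5 draws
  a <- calibrate_amplitude(3, floor_amp)
  sd_c <- floor_amp * sqrt(2 / pi)
  set.seed(42)
  mods <- sqrt((a + rnorm(1e5) * sd_c)^2 + (rnorm(1e5) * sd_c)^2)
  expect_equal(mean(mods), 3 * floor_amp, tolerance = 0.01)

  # closed-form Rice mean against the same oracle
  expect_equal(rice_mean(a, sd_c), mean(mods), tolerance = 0.01)
})

test_that("seeded block synthesis is bit-identical and puts local maxima at the configured harmonics", {
  p <- generative_params()
  b1 <- simulate_block_eeg(p, target_log_base_snr = 1.5,
                           target_log_doublet_snr = 1.2, seed = 7)
  b2 <- simulate_block_eeg(p, target_log_base_snr = 1.5,
                           target_log_doublet_snr = 1.2, seed = 7)
  expect_identical(b1$data, b2$data)

  spec <- amplitude_spectrum(b1)
  occ <- colMeans(spec$amp[roi_cluster_channels(), ])
  for (f in seq(3, 24, by = 3)) {
    bin <- freqtag:::freq_bin(spec$freqs, f)
    expect_gt(occ[bin], max(occ[c(bin - 1, bin + 1)]))
  }
})

test_that("with no doublet signal the measured doublet-frequency SNR stays at the noise floor", {
  p <- generative_params()
  roi <- roi_cluster_channels()
  vals <- vapply(1:40, function(i) {
    b <- simulate_block_eeg(p, target_log_base_snr = 0.4,
                            target_log_doublet_snr = 0, seed = 200 + i)
    s <- snr_spectrum(amplitude_spectrum(b))
    combined_snr(s, roi, c(3, 9, 15, 21))
  }, numeric(1))
  expect_gt(mean(vals), 0.95)
  expect_lt(mean(vals), 1.10)
})

test_that("the measured ROI log base SNR recovers the generative target", {
  p <- generative_params()
  roi <- roi_cluster_channels()
  vals <- vapply(1:60, function(i) {
    b <- simulate_block_eeg(p, target_log_base_snr = 0.302,
                            target_log_doublet_snr = 0, seed = 300 + i)
    s <- snr_spectrum(amplitude_spectrum(b))
    log(combined_snr(s, roi, c(6, 12, 18, 24)))
  }, numeric(1))
  expect_equal(mean(vals), 0.302, tolerance = 0.03 / 0.302)
})

test_that("rescaling the whole channel gain map leaves the synthesised SNRs unchanged", {
  p1 <- generative_params()
  p2 <- generative_params(gain = 3 * occipital_gain_map())
  b1 <- simulate_block_eeg(p1, target_log_base_snr = 0.5, seed = 5)
  b2 <- simulate_block_eeg(p2, target_log_base_snr = 0.5, seed = 5)
  expect_identical(b1$data, b2$data) # gains are normalised to their maximum
})

test_that("simulated cohorts have 80 sessions, monotone attrition, and the configured valid rate", {
  co <- simulate_cohort(seed = 10)
  expect_equal(nrow(co$sessions), 80L)
  expect_equal(as.vector(table(co$sessions$timepoint)), c(30L, 27L, 23L))

  t1 <- co$sessions$subject[co$sessions$timepoint == "T1"]
  t2 <- co$sessions$subject[co$sessions$timepoint == "T2"]
  t3 <- co$sessions$subject[co$sessions$timepoint == "T3"]
  expect_true(all(t3 %in% t2))
  expect_true(all(t2 %in% t1))

  # learning-index identity holds exactly in the feature table
  expect_equal(co$blocks$learning_index,
               co$blocks$log_doublet_snr - co$blocks$log_base_snr)

  # long-run valid fraction near the configured 76.42%
  valid <- unlist(lapply(1:4, function(s) simulate_cohort(seed = s)$raw$valid))
  expect_equal(100 * mean(valid), 76.42, tolerance = 2 / 76.42)

  # determinism of the master seed
  co2 <- simulate_cohort(seed = 10)
  expect_identical(co$blocks, co2$blocks)
  expect_identical(co$trials, co2$trials)
})

test_that("test-phase behaviour follows the configured linear link and recovers its slope", {
  p0 <- generative_params()
  quiet <- generative_params(
    behaviour = utils::modifyList(p0$behaviour,
                                  list(residual_sd = 0, trial_sd_s = 0))
  )
  tr <- simulate_test_behaviour(quiet, learning_index = 0.2, timepoint = "T3",
                                seed = 1)
  ps <- preference_score(tr$looking_s, tr$type)
  expect_equal(ps$score, 4.421 * 0.2 + 0.484, tolerance = 1e-12)
  expect_identical(tr$type[1], "familiar")

  silent <- generative_params(
    behaviour = utils::modifyList(p0$behaviour,
                                  list(intercepts = c(t1 = 0, t2 = 0, t3 = 0),
                                       slopes = c(t1 = 0, t2 = 0, t3 = 0),
                                       residual_sd = 0, trial_sd_s = 0))
  )
  tr0 <- simulate_test_behaviour(silent, 0.4, "T2", seed = 2)
  expect_equal(preference_score(tr0$looking_s, tr0$type)$score, 0)

  # regression recovery of the T3 slope over 500 simulated subjects
  set.seed(99)
  li <- runif(500, -0.3, 0.5)
  scores <- vapply(li, function(l) {
    tr <- simulate_test_behaviour(p0, l, "T3")
    preference_score(tr$looking_s, tr$type)$score
  }, numeric(1))
  fit <- summary(stats::lm(scores ~ li))$coefficients
  expect_lt(abs(fit["li", "Estimate"] - 4.421) / fit["li", "Std. Error"], 2)
})

test_that("trial looking times are truncated to the 7-s trial window", {
  p <- generative_params()
  set.seed(4)
  for (i in 1:50) {
    tr <- simulate_test_behaviour(p, rnorm(1, 0, 0.3),
                                  sample(c("T1", "T2", "T3"), 1))
    expect_true(all(tr$looking_s >= 0 & tr$looking_s <= 7))
  }
})
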