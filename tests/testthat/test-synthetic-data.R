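test_that("eye-trace generator is deterministic and counts saccades sensibly", {
  tr1 <- simulate_eye_trace(okn_params(), duration_s = 10, seed = 4)
  tr2 <- simulate_eye_trace(okn_params(), duration_s = 10, seed = 4)
  expect_identical(tr1$x_deg, tr2$x_deg)
  expect_identical(true_saccades(tr1), true_saccades(tr2))
  tr3 <- simulate_eye_trace(okn_params(), duration_s = 10, seed = 5)
  expect_false(identical(tr1$x_deg, tr3$x_deg))

  # ~20 saccades expected in 20 s at a 1000 ms mean interval; the refractory
  # floor and drift cap keep the count within a Poisson-like band
  tr <- simulate_eye_trace(okn_params(intersaccadic_interval_mean = 1000),
                           duration_s = 20, seed = 1)
  expect_gt(nrow(true_saccades(tr)), 10)
  expect_lt(nrow(true_saccades(tr)), 35)
})

test_that("zero-amplitude parameters give a pure slow phase", {
  tr <- simulate_eye_trace(okn_params(saccade_amplitude_mean = 0),
                           duration_s = 5, seed = 2)
  expect_equal(nrow(true_saccades(tr)), 0)
  # constant-velocity drift only: speed never near the criterion
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("generator rejects invalid inputs", {
  expect_error(simulate_eye_trace(okn_params(), duration_s = 0), "positive")
  expect_error(simulate_eye_trace(okn_params(), duration_s = -1), "positive")
  expect_error(okn_params(sampling_rate = 0), "sampling_rate")
  expect_error(okn_params(saccade_peak_speed = 50), "peak_speed")
})

test_that("spike trains recover the tuning-line rate", {
  # intercept-only rate at straight ahead: the worked-example fit
  pop <- tibble::tibble(neuron_id = 1, slope_a = 0.108, intercept_b = 11.77)
  sp <- simulate_spike_trains(pop, heading_deg = 0, duration_s = 100,
                              seed = 10)
  rate <- nrow(sp) / 100
  expect_lt(abs(rate - 11.77), 3 * sqrt(11.77 / 100))

  # slope contribution at 30 deg: 0.2 * 30 + 10 = 16 spikes/s
  pop2 <- tibble::tibble(neuron_id = 1, slope_a = 0.2, intercept_b = 10)
  sp2 <- simulate_spike_trains(pop2, heading_deg = 30, duration_s = 100,
                               seed = 11)
  expect_lt(abs(nrow(sp2) / 100 - 16), 3 * sqrt(16 / 100))
})

test_that("a clamped-to-zero rate emits no spikes", {
  pop <- tibble::tibble(neuron_id = 1, slope_a = 1, intercept_b = -50)
  sp <- simulate_spike_trains(pop, heading_deg = 0, duration_s = 20,
                              seed = 1)
  expect_equal(nrow(sp), 0)
})

test_that("a constant 0.5 gain halves the long-run rate", {
  # 0.5 * (0.2 * 30 + 10) = 8 spikes/s; onsets tile the whole trace so the
  # kernel window covers every time point
  pop <- tibble::tibble(neuron_id = 1, slope_a = 0.2, intercept_b = 10)
  half <- tibble::tibble(time_ms = peri_bins(), gain = 0.5)
  onsets <- seq(200, 120 * 1000, by = 600)
  sp <- simulate_spike_trains(pop, heading_deg = 30, duration_s = 120,
                              saccade_onsets = onsets,
                              kernel_assignment = list(half), seed = 3)
  expect_lt(abs(nrow(sp) / 120 - 8), 3 * sqrt(8 / 120))
})

test_that("gain kernels are flank-normalized to 1", {
  for (k in model_kernels()) {
    fm <- mean(k$gain[k$time_ms < -100 | k$time_ms >= 100])
    expect_lt(abs(fm - 1), 1e-9)
  }
  deep <- gaussian_kernel(0.9, center_ms = 0, width_ms = 80)
  fm <- mean(deep$gain[deep$time_ms < -100 | deep$time_ms >= 100])
  expect_lt(abs(fm - 1), 1e-9)
  expect_error(suppression_kernel(peri_bins(), rep(0, 33)), "flank")
})

test_that("behavioral generator obeys its report equation", {
  # no compression, no noise, no bias: reports equal true headings
  p0 <- behavioral_params(trials_per_heading = 20,
                          compression_profile = function(t) rep(0, length(t)),
                          report_noise_sd = 0)
  tr0 <- simulate_behavioral_trials(p0, seed = 1)
  expect_equal(tr0$reported_heading_deg, tr0$true_heading_deg)

  # full compression: every report collapses to the gaze centre (0 deg)
  p1 <- behavioral_params(trials_per_heading = 20,
                          compression_profile = function(t) rep(1, length(t)),
                          report_noise_sd = 0)
  tr1 <- simulate_behavioral_trials(p1, seed = 2)
  expect_equal(tr1$reported_heading_deg, rep(0, nrow(tr1)))

  # with gaze 15 deg left, full compression pulls every heading to -15
  p2 <- behavioral_params(trials_per_heading = 20,
                          compression_profile = function(t) rep(1, length(t)),
                          report_noise_sd = 0, gaze_offset = -15)
  tr2 <- simulate_behavioral_trials(p2, seed = 3)
  expect_equal(tr2$reported_heading_deg, rep(-15, nrow(tr2)))

  expect_error(behavioral_params(headings = numeric(0)), "non-empty")
})

test_that("fixation reports have the requested noise SD and uniform onsets", {
  p <- behavioral_params(trials_per_heading = 400, report_noise_sd = 2)
  tr <- simulate_behavioral_trials(p, condition = "fixation", seed = 6)
  per_heading_sd <- tapply(tr$reported_heading_deg, tr$true_heading_deg, sd)
  expect_true(all(abs(per_heading_sd - 2) < 0.3))

  sac <- simulate_behavioral_trials(p, seed = 7)
  expect_true(all(abs(sac$onset_ms) <= 200))
  # uniform on [-200, 200]: SD = 400 / sqrt(12)
  expect_lt(abs(sd(sac$onset_ms) - 400 / sqrt(12)), 6)
  expect_lt(abs(mean(sac$onset_ms)), 10)
})

test_that("generators are reproducible under a fixed seed", {
  p <- behavioral_params(trials_per_heading = 10)
  expect_identical(simulate_behavioral_trials(p, seed = 9),
                   simulate_behavioral_trials(p, seed = 9))
  pop <- virtual_population(seed = 3)
  expect_identical(pop, virtual_population(seed = 3))
  expect_identical(
    simulate_spike_trains(pop[1:5, ], 15, 2, seed = 8),
    simulate_spike_trains(pop[1:5, ], 15, 2, seed = 8)
  )
})

test_that("virtual population has the configured subpopulation split", {
  pop <- virtual_population(seed = 1)
  expect_equal(nrow(pop), 71)
  expect_equal(sum(pop$slope_a < 0), 38)
  expect_equal(sum(pop$slope_a > 0), 33)
  expect_true(all(pop$intercept_b >= 0))
})
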