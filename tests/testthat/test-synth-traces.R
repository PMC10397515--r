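test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(duration_s = 0), "duration_s")
  expect_error(sim_config(duration_s = 1, noise_sd_pa = -1), "noise_sd_pa")
  expect_error(sim_config(duration_s = 1, tau_rise_ms = 10, tau_decay_ms = 5),
               "tau_decay_ms")
  expect_error(sim_config(duration_s = 1, t_drug_s = 2), "t_drug_s")
  expect_error(sim_config(duration_s = 1, capacitance_pf = -3),
               "capacitance_pf")
})

test_that("noiseless event-free trace is exactly the holding current", {
  cfg <- sim_config(duration_s = 1.5, i_hold_pa = -45, noise_sd_pa = 0,
                    event_rate_hz = 0, tonic_shift_pa = 0)
  sim <- simulate_trace(cfg)
  expect_length(sim$trace$samples, round(1.5 * cfg$sampling_rate_hz))
  expect_true(all(sim$trace$samples == -45))
  expect_identical(sim$truth$event_times_s, numeric(0))
})

test_that("identical config and seed give bit-identical traces", {
  cfg <- sim_config(duration_s = 2, seed = 99)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- simulate_trace(cfg2)
  expect_gt(max(abs(a$trace$samples - c$trace$samples)), 1)
})

test_that("realized event counts follow the Poisson law", {
  # 200 seeds at 2 Hz for 100 s; low sampling rate keeps this cheap and
  # does not affect the arrival process
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(duration_s = 100, sampling_rate_hz = 100,
                      noise_sd_pa = 0, event_rate_hz = 2, seed = s)
    length(simulate_trace(cfg)$truth$event_times_s)
  }, 0)
  se <- sqrt(200) / sqrt(200)  # sd of Poisson(200) over 200 replicates
  expect_lt(abs(mean(counts) - 200), 3 * se)
})

test_that("post-drug steady state equals i_hold + tonic_shift exactly", {
  cfg <- sim_config(duration_s = 10, i_hold_pa = -40, noise_sd_pa = 0,
                    event_rate_hz = 0, tonic_shift_pa = -25, t_drug_s = 2,
                    washin_tau_s = 0)  # step wash-in isolates the asymptote
  sim <- simulate_trace(cfg)
  fs <- cfg$sampling_rate_hz
  expect_true(all(sim$trace$samples[(3 * fs):(10 * fs)] == -65))
  expect_true(all(sim$trace$samples[1:(2 * fs - 1)] == -40))
  expect_identical(sim$truth$i_hold_post_pa - sim$truth$i_hold_pre_pa,
                   sim$truth$tonic_shift_pa)
})

test_that("wash-in follows the single-exponential approach", {
  cfg <- sim_config(duration_s = 100, sampling_rate_hz = 100,
                    noise_sd_pa = 0, event_rate_hz = 0,
                    tonic_shift_pa = -30, t_drug_s = 10, washin_tau_s = 30)
  sim <- simulate_trace(cfg)
  t <- (seq_along(sim$trace$samples) - 1) / 100
  expected <- -50 + ifelse(t >= 10, -30 * (1 - exp(-(t - 10) / 30)), 0)
  expect_equal(sim$trace$samples, expected, tolerance = 1e-12)
})

test_that("event kernels integrate to the analytic value", {
  # peak-normalized difference of exponentials
  kern <- tonicgaba:::ipsc_kernel(1, 10, 10000)
  expect_equal(max(kern), 1, tolerance = 1e-4)
  expect_equal(sum(kern) / 10000,
               tonicgaba:::ipsc_kernel_integral_s(1, 10),
               tolerance = 2e-3)
  # trace integral = -sum(amplitudes) * kernel integral (no noise/shift)
  cfg <- sim_config(duration_s = 30, noise_sd_pa = 0, event_rate_hz = 0.2,
                    event_amp_cv = 0.3, seed = 11)
  sim <- simulate_trace(cfg)
  stopifnot(length(sim$truth$event_times_s) > 0,
            max(sim$truth$event_times_s) < 29.5)  # no end clipping
  got <- sum(sim$trace$samples - cfg$i_hold_pa) / cfg$sampling_rate_hz
  want <- -sum(sim$truth$event_amps_pa) *
    tonicgaba:::ipsc_kernel_integral_s(1, 10)
  expect_equal(got, want, tolerance = 2e-3)
})

test_that("sample mean of a noisy flat trace converges at sigma/sqrt(N)", {
  devs <- vapply(1:40, function(s) {
    cfg <- sim_config(duration_s = 1, i_hold_pa = -50, noise_sd_pa = 3,
                      event_rate_hz = 0, seed = s)
    mean(simulate_trace(cfg)$trace$samples) + 50
  }, 0)
  # low-pass filtering correlates samples, inflating the SE somewhat; all
  # deviations should still sit within a few nominal standard errors
  expect_lt(max(abs(devs)), 8 * 3 / sqrt(10000))
  expect_lt(abs(mean(devs)), 3 * 3 / sqrt(10000 * 40))
})

test_that("cohorts are reproducible and disperse between cells", {
  cfg <- sim_config(duration_s = 1, seed = 5)
  one <- simulate_cohort(1, cfg, seed = 7)
  one2 <- simulate_cohort(1, cfg, seed = 7)
  expect_identical(one[[1]]$trace$samples, one2[[1]]$trace$samples)
  expect_identical(one[[1]]$truth$tonic_shift_pa, cfg$tonic_shift_pa)

  coh <- simulate_cohort(
    7, sim_config(duration_s = 1, tonic_shift_pa = -20, t_drug_s = 0.5),
    between_cell_sd = list(tonic_shift_pa = 5), seed = 3)
  shifts <- vapply(coh, function(s) s$truth$tonic_shift_pa, 0)
  expect_length(unique(shifts), 7)
  expect_error(simulate_cohort(3, cfg,
                               between_cell_sd = list(tonic_shift_pa = -1)),
               ">= 0")
  expect_error(simulate_cohort(3, cfg,
                               between_cell_sd = list(nope = 1)),
               "unknown")
})

test_that("step response obeys Ohm's law and reaches steady state", {
  cfg <- sim_config(duration_s = 2.5, noise_sd_pa = 0, event_rate_hz = 0)
  st <- simulate_step_response(100, tau_membrane_ms = 10, i_step_pa = -10,
                               config = cfg)
  fs <- cfg$sampling_rate_hz
  i_on <- floor(0.5 * fs) + 1L
  i_off <- floor(1.5 * fs)
  last100 <- st$voltage_samples[(i_off - round(0.1 * fs) + 1L):i_off]
  # last 100 ms of a 1-s pulse with tau = 10 ms: within 0.1% of asymptote
  expect_equal(mean(last100), -70 - 1.0, tolerance = 0.001 * 1.0 / 71)
  expect_true(all(st$voltage_samples[1:(i_on - 1L)] == -70))
  expect_error(simulate_step_response(-5, config = cfg), "r_input")
  expect_error(simulate_step_response(100, config = cfg,
                                      pulse_start_s = 2, pulse_duration_s = 1),
               "within the trace")
})
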