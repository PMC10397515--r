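#' Bi-exponential synaptic event kernel
#'
#' Difference-of-exponentials waveform normalized so its peak equals 1, the
#' standard phenomenological shape for a synaptic current with a fast rise
#' and slower decay.
#'
#' @param tau_rise_ms,tau_decay_ms Time constants in ms, decay > rise > 0.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_decay_taus Kernel length in multiples of the decay time
#'   constant; 8 truncates below 0.04% of peak.
#' @return Numeric vector of kernel samples starting at event onset.
#' @keywords internal
ipsc_kernel <- function(tau_rise_ms, tau_decay_ms, sampling_rate_hz,
                        n_decay_taus = 8) {
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  n <- max(2L, ceiling(n_decay_taus * td * sampling_rate_hz))
  t <- seq_len(n) / sampling_rate_hz
  t_peak <- (tr * td / (td - tr)) * log(td / tr)
  norm <- exp(-t_peak / td) - exp(-t_peak / tr)
  (exp(-t / td) - exp(-t / tr)) / norm
}

# Zero-phase low-pass for the recording noise: the squared-magnitude
# response of a second-order Butterworth applied in the frequency domain
# (real symmetric transfer function, so no phase distortion). Input is
# padded to an FFT-friendly length and truncated back.
lowpass_noise <- function(x, cutoff_hz, fs) {
  n <- length(x)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(np - n))
  k <- seq_len(np) - 1L
  f <- ifelse(k <= np / 2, k, k - np) * (fs / np)
  h <- 1 / sqrt(1 + (f / cutoff_hz)^4)
  Re(stats::fft(stats::fft(xp) * h, inverse = TRUE) / np)[seq_len(n)]
}

# Analytic integral (in seconds) of the peak-normalized kernel; used by
# property tests that compare trace integrals to closed form.
ipsc_kernel_integral_s <- function(tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  t_peak <- (tr * td / (td - tr)) * log(td / tr)
  norm <- exp(-t_peak / td) - exp(-t_peak / tr)
  (td - tr) / norm
}

#' Simulate a whole-cell voltage-clamp current trace with known ground truth
#'
#' Generates `i_hold + washed-in tonic shift + sIPSC kernels + filtered
#' Gaussian noise` at the configured sampling rate. Spontaneous IPSCs arrive
#' as a Poisson process (rate scaled by `post_drug_event_scale` after
#' `t_drug_s`), each an inward difference-of-exponentials kernel whose peak
#' magnitude is drawn from a lognormal law. The tonic shift approaches its
#' steady-state value with a single-exponential wash-in. White noise is
#' passed through a zero-phase low-pass (the squared-magnitude response of
#' a second-order Butterworth, applied in the frequency domain) at
#' `filter_cutoff_hz`, standing in for the acquisition Bessel filter.
#'
#' @param config A [sim_config()].
#' @return A list with components `trace` (a [current_trace()]) and
#'   `truth` (a `ground_truth` list: `event_times_s`, `event_amps_pa`
#'   as positive magnitudes, `i_hold_pre_pa`, `i_hold_post_pa`,
#'   `tonic_shift_pa`, `capacitance_pf`, and the realized `seed`).
#' @examples
#' sim <- simulate_trace(sim_config(duration_s = 2, event_rate_hz = 5,
#'                                  seed = 42))
#' length(sim$trace$samples)  # 20000 samples at 10 kHz
#' @export
simulate_trace <- function(config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  baseline <- rep(config$i_hold_pa, n)
  if (!is.na(config$t_drug_s) && config$tonic_shift_pa != 0) {
    dt <- t - config$t_drug_s
    on <- dt >= 0
    washin <- if (config$washin_tau_s > 0) {
      1 - exp(-dt[on] / config$washin_tau_s)
    } else {
      1
    }
    baseline[on] <- baseline[on] + config$tonic_shift_pa * washin
  }

  drawn <- withr::with_seed(config$seed, {
    # arrivals: piecewise-homogeneous Poisson around the drug time
    t_drug <- if (is.na(config$t_drug_s)) config$duration_s else config$t_drug_s
    lam_pre <- config$event_rate_hz
    lam_post <- config$event_rate_hz * config$post_drug_event_scale
    n_pre <- stats::rpois(1, lam_pre * t_drug)
    n_post <- stats::rpois(1, lam_post * (config$duration_s - t_drug))
    times <- sort(c(stats::runif(n_pre, 0, t_drug),
                    stats::runif(n_post, t_drug, config$duration_s)))
    amps <- if (length(times) > 0) {
      if (config$event_amp_cv > 0) {
        sdlog <- sqrt(log(1 + config$event_amp_cv^2))
        meanlog <- log(config$event_amp_mean_pa) - sdlog^2 / 2
        stats::rlnorm(length(times), meanlog, sdlog)
      } else {
        rep(config$event_amp_mean_pa, length(times))
      }
    } else {
      numeric(0)
    }
    noise <- if (config$noise_sd_pa > 0) {
      stats::rnorm(n, 0, config$noise_sd_pa)
    } else {
      numeric(0)
    }
    list(times = times, amps = amps, noise = noise)
  })

  samples <- baseline
  if (length(drawn$times) > 0) {
    kern <- ipsc_kernel(config$tau_rise_ms, config$tau_decay_ms, fs)
    lk <- length(kern)
    idx0 <- pmin(n, floor(drawn$times * fs) + 1L)
    for (e in seq_along(idx0)) {
      i1 <- idx0[e]
      i2 <- min(n, i1 + lk - 1L)
      samples[i1:i2] <- samples[i1:i2] - drawn$amps[e] * kern[seq_len(i2 - i1 + 1L)]
    }
  }
  if (length(drawn$noise) > 0) {
    if (config$filter_cutoff_hz < fs / 2) {
      drawn$noise <- lowpass_noise(drawn$noise, config$filter_cutoff_hz, fs)
    }
    samples <- samples + drawn$noise
  }

  trace <- current_trace(
    samples = samples,
    sampling_rate_hz = fs,
    t_drug_s = config$t_drug_s,
    capacitance_pf = config$capacitance_pf,
    cell_id = "sim",
    group_label = "",
    condition = ""
  )
  truth <- structure(
    list(event_times_s = drawn$times,
         event_amps_pa = drawn$amps,
         i_hold_pre_pa = config$i_hold_pa,
         i_hold_post_pa = config$i_hold_pa + config$tonic_shift_pa,
         tonic_shift_pa = config$tonic_shift_pa,
         capacitance_pf = config$capacitance_pf,
         seed = config$seed),
    class = "ground_truth"
  )
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of cells with between-cell parameter dispersion
#'
#' Draws per-cell simulation parameters around a template configuration
#' (independent Gaussian jitter per listed field) and simulates one trace
#' per cell, each from a sub-seed derived reproducibly from `seed`. This
#' emulates the between-cell variability of a recorded group (e.g. seven
#' SST cells vs seven PV cells).
#'
#' @param n_cells Number of cells, at least 1.
#' @param config_template A [sim_config()] giving the group-level parameter
#'   values.
#' @param between_cell_sd Named list of per-field standard deviations, e.g.
#'   `list(tonic_shift_pa = 6, i_hold_pa = 10, capacitance_pf = 8)`. All
#'   values must be non-negative and name numeric `sim_config` fields.
#' @param seed Integer master seed.
#' @param id_prefix Prefix for generated cell ids.
#' @return A list of length `n_cells`; each element is the
#'   `list(trace, truth)` returned by [simulate_trace()], with `cell_id`
#'   set to `"<id_prefix><i>"`.
#' @export
simulate_cohort <- function(n_cells, config_template,
                            between_cell_sd = list(),
                            seed = config_template$seed,
                            id_prefix = "cell") {
  if (length(n_cells) != 1 || is.na(n_cells) || n_cells < 1)
    stop("n_cells must be a single integer >= 1", call. = FALSE)
  n_cells <- as.integer(n_cells)
  validate_sim_config(config_template)
  if (length(between_cell_sd) > 0) {
    bad <- setdiff(names(between_cell_sd), names(config_template))
    if (length(bad) > 0)
      stop("unknown sim_config field(s) in between_cell_sd: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(unlist(between_cell_sd) < 0))
      stop("between_cell_sd values must be >= 0", call. = FALSE)
  }
  draws <- withr::with_seed(as.integer(seed), {
    sub_seeds <- sample.int(.Machine$integer.max, n_cells)
    jitter <- lapply(names(between_cell_sd), function(f) {
      stats::rnorm(n_cells, 0, between_cell_sd[[f]])
    })
    names(jitter) <- names(between_cell_sd)
    list(sub_seeds = sub_seeds, jitter = jitter)
  })
  lapply(seq_len(n_cells), function(i) {
    cfg <- config_template
    for (f in names(draws$jitter))
      cfg[[f]] <- cfg[[f]] + draws$jitter[[f]][i]
    cfg$seed <- draws$sub_seeds[i]
    validate_sim_config(cfg)
    sim <- simulate_trace(cfg)
    sim$trace$cell_id <- sprintf("%s%02d", id_prefix, i)
    sim
  })
}

#' Simulate a current-clamp voltage response to a hyperpolarizing step
#'
#' Single-compartment RC response: during the pulse the membrane voltage
#' relaxes exponentially toward `v_baseline + i_step * R`, and back to
#' baseline afterwards, with optional Gaussian voltage noise. Used to
#' validate the input-resistance estimator against a known resistance.
#'
#' @param r_input_mohm True input resistance in megaohms, positive.
#' @param tau_membrane_ms Membrane time constant in ms.
#' @param i_step_pa Injected current step in pA (the standard protocol uses
#'   a -10 pA, 1-s hyperpolarizing pulse).
#' @param config A [sim_config()] providing duration, sampling rate,
#'   baseline voltage (`v_hold_mv`) and seed.
#' @param pulse_start_s,pulse_duration_s Pulse window in seconds; must fit
#'   inside the trace and the pulse must exceed 0.1 s so a last-100-ms
#'   steady-state window exists.
#' @param noise_sd_mv Gaussian voltage noise standard deviation in mV.
#' @return A `step_response` object (see [input_resistance()]).
#' @export
simulate_step_response <- function(r_input_mohm, tau_membrane_ms = 20,
                                   i_step_pa = -10, config,
                                   pulse_start_s = 0.5,
                                   pulse_duration_s = 1,
                                   noise_sd_mv = 0) {
  validate_sim_config(config)
  if (r_input_mohm <= 0)
    stop("r_input_mohm must be > 0", call. = FALSE)
  if (pulse_duration_s <= 0.1)
    stop("pulse_duration_s must exceed 0.1 s", call. = FALSE)
  if (pulse_start_s < 0 ||
      pulse_start_s + pulse_duration_s > config$duration_s)
    stop("pulse window must lie within the trace", call. = FALSE)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  tau <- tau_membrane_ms / 1000
  # pA * MOhm = 1e-12 A * 1e6 Ohm = 1e-6 V = 1e-3 mV
  dv <- i_step_pa * r_input_mohm / 1000
  v <- rep(config$v_hold_mv, n)
  during <- t >= pulse_start_s & t < pulse_start_s + pulse_duration_s
  after <- t >= pulse_start_s + pulse_duration_s
  v[during] <- v[during] + dv * (1 - exp(-(t[during] - pulse_start_s) / tau))
  v_end <- dv * (1 - exp(-pulse_duration_s / tau))
  v[after] <- v[after] +
    v_end * exp(-(t[after] - pulse_start_s - pulse_duration_s) / tau)
  if (noise_sd_mv > 0) {
    v <- v + withr::with_seed(config$seed, stats::rnorm(n, 0, noise_sd_mv))
  }
  step_response(voltage_samples = v, sampling_rate_hz = fs,
                i_step_pa = i_step_pa, pulse_start_s = pulse_start_s,
                pulse_duration_s = pulse_duration_s, cell_id = "sim")
}
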