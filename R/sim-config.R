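#' Simulation configuration for synthetic voltage-clamp traces
#'
#' Bundles and validates every parameter of the synthetic recording model:
#' a stationary holding current with Gaussian recording noise, superimposed
#' inward spontaneous IPSCs (Poisson arrivals, bi-exponential kernels,
#' lognormal amplitudes), and a drug-induced sustained baseline shift that
#' washes in exponentially. Inward currents are negative throughout.
#'
#' @param duration_s Recording length in seconds. Must be positive.
#' @param sampling_rate_hz Sampling rate in Hz. Default 10000, the usual
#'   acquisition rate for whole-cell recordings.
#' @param i_hold_pa Baseline holding current in pA (inward-negative).
#' @param noise_sd_pa Standard deviation of the white recording noise in pA
#'   before low-pass filtering. Must be non-negative.
#' @param event_rate_hz Poisson arrival rate of spontaneous IPSCs in Hz.
#' @param event_amp_mean_pa Mean sIPSC peak amplitude magnitude in pA.
#'   Amplitudes are drawn lognormal and applied as negative (inward)
#'   deflections.
#' @param event_amp_cv Coefficient of variation of the sIPSC amplitude law.
#' @param tau_rise_ms,tau_decay_ms Bi-exponential kernel time constants in
#'   ms; `tau_decay_ms > tau_rise_ms > 0` is required.
#' @param tonic_shift_pa Signed sustained change of holding current after
#'   drug application, in pA. Negative = inward (agonist such as THIP),
#'   positive = outward (block by an antagonist such as SR95531).
#' @param t_drug_s Time of drug application in seconds, or `NA` for a
#'   drug-free trace.
#' @param washin_tau_s Time constant of the single-exponential approach of
#'   the tonic shift to steady state, in seconds.
#' @param post_drug_event_scale Factor applied to the sIPSC rate after the
#'   drug (1 = unchanged, as for THIP; 0 = events abolished, as under
#'   SR95531).
#' @param filter_cutoff_hz Low-pass cutoff in Hz applied to the recording
#'   noise, emulating the acquisition Bessel filter. Cutoffs at or above
#'   the Nyquist frequency disable filtering.
#' @param v_hold_mv Holding potential in mV (metadata only).
#' @param capacitance_pf Cell capacitance in pF, or `NA` when not measured.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical traces.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_trace()], [simulate_cohort()]
#' @export
sim_config <- function(duration_s,
                       sampling_rate_hz = 10000,
                       i_hold_pa = -50,
                       noise_sd_pa = 3,
                       event_rate_hz = 2,
                       event_amp_mean_pa = 30,
                       event_amp_cv = 0.5,
                       tau_rise_ms = 1,
                       tau_decay_ms = 10,
                       tonic_shift_pa = 0,
                       t_drug_s = NA_real_,
                       washin_tau_s = 30,
                       post_drug_event_scale = 1,
                       filter_cutoff_hz = 4000,
                       v_hold_mv = -70,
                       capacitance_pf = NA_real_,
                       seed = 1L) {
  cfg <- list(
    duration_s = as.numeric(duration_s),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    i_hold_pa = as.numeric(i_hold_pa),
    noise_sd_pa = as.numeric(noise_sd_pa),
    event_rate_hz = as.numeric(event_rate_hz),
    event_amp_mean_pa = as.numeric(event_amp_mean_pa),
    event_amp_cv = as.numeric(event_amp_cv),
    tau_rise_ms = as.numeric(tau_rise_ms),
    tau_decay_ms = as.numeric(tau_decay_ms),
    tonic_shift_pa = as.numeric(tonic_shift_pa),
    t_drug_s = as.numeric(t_drug_s),
    washin_tau_s = as.numeric(washin_tau_s),
    post_drug_event_scale = as.numeric(post_drug_event_scale),
    filter_cutoff_hz = as.numeric(filter_cutoff_hz),
    v_hold_mv = as.numeric(v_hold_mv),
    capacitance_pf = as.numeric(capacitance_pf),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x A `sim_config` object (or a plain list with the same fields).
#' @export
validate_sim_config <- function(x) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field, allow_na = FALSE) {
    v <- x[[field]]
    if (length(v) != 1) fail(field, "must be a single value")
    if (!allow_na && (is.na(v) || !is.finite(v))) fail(field, "must be finite")
    v
  }
  if (num1("duration_s") <= 0) fail("duration_s", "must be > 0")
  if (num1("sampling_rate_hz") <= 0) fail("sampling_rate_hz", "must be > 0")
  if (num1("noise_sd_pa") < 0) fail("noise_sd_pa", "must be >= 0")
  if (num1("event_rate_hz") < 0) fail("event_rate_hz", "must be >= 0")
  if (num1("event_amp_mean_pa") <= 0) fail("event_amp_mean_pa", "must be > 0")
  if (num1("event_amp_cv") < 0) fail("event_amp_cv", "must be >= 0")
  tr <- num1("tau_rise_ms"); td <- num1("tau_decay_ms")
  if (!(td > tr && tr > 0))
    fail("tau_decay_ms", "must satisfy tau_decay_ms > tau_rise_ms > 0")
  num1("i_hold_pa"); num1("tonic_shift_pa"); num1("v_hold_mv")
  td_s <- num1("t_drug_s", allow_na = TRUE)
  if (!is.na(td_s) && (td_s < 0 || td_s > x$duration_s))
    fail("t_drug_s", "must lie within [0, duration_s]")
  if (num1("washin_tau_s") < 0) fail("washin_tau_s", "must be >= 0")
  if (num1("post_drug_event_scale") < 0)
    fail("post_drug_event_scale", "must be >= 0")
  if (num1("filter_cutoff_hz") <= 0) fail("filter_cutoff_hz", "must be > 0")
  cap <- num1("capacitance_pf", allow_na = TRUE)
  if (!is.na(cap) && cap <= 0) fail("capacitance_pf", "must be > 0 when given")
  if (is.na(x$seed)) fail("seed", "must be an integer")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %.6g s at %g Hz, i_hold %.6g pA, noise sd %.6g pA\n",
              x$duration_s, x$sampling_rate_hz, x$i_hold_pa, x$noise_sd_pa))
  cat(sprintf("  sIPSC: %.6g Hz, amp %.6g pA (cv %.6g), tau %g/%g ms\n",
              x$event_rate_hz, x$event_amp_mean_pa, x$event_amp_cv,
              x$tau_rise_ms, x$tau_decay_ms))
  if (!is.na(x$t_drug_s))
    cat(sprintf("  drug at %.6g s: shift %.6g pA, washin tau %.6g s, event scale %.6g\n",
                x$t_drug_s, x$tonic_shift_pa, x$washin_tau_s,
                x$post_drug_event_scale))
  invisible(x)
}
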