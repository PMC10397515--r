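#' Input resistance from a current-step voltage response
#'
#' Computes the input resistance as the ratio of the steady-state voltage
#' response to the injected current step: the baseline is the mean of the
#' 100 ms immediately preceding pulse onset, the steady state is the mean
#' of the last 100 ms of the pulse, and
#' `R = (v_steady - v_baseline) / i_step`. Unit algebra: voltages are in
#' mV and currents in pA, and 1 mV / 1 pA = 1e-3 V / 1e-12 A = 1e9 Ohm =
#' 1000 MOhm, so the mV/pA ratio is multiplied by 1000 to give MOhm.
#'
#' @param step A [step_response()]. At least 100 ms of pre-pulse baseline
#'   must exist, and the pulse must be longer than 100 ms.
#' @return A `passive_props` object: `r_input_mohm`, `v_baseline_mv`,
#'   `v_steady_mv`, `i_step_pa`, `cell_id`.
#' @examples
#' cfg <- sim_config(duration_s = 2.5, noise_sd_pa = 0, event_rate_hz = 0)
#' st <- simulate_step_response(100, tau_membrane_ms = 10, i_step_pa = -10,
#'                              config = cfg)
#' input_resistance(st)$r_input_mohm  # ~100 MOhm
#' @export
input_resistance <- function(step) {
  stopifnot(inherits(step, "step_response"))
  fs <- step$sampling_rate_hz
  w <- round(0.1 * fs)
  if (step$pulse_duration_s <= 0.1)
    stop("pulse shorter than 100 ms: no steady-state window", call. = FALSE)
  on_idx <- floor(step$pulse_start_s * fs) + 1L
  off_idx <- floor((step$pulse_start_s + step$pulse_duration_s) * fs)
  off_idx <- min(off_idx, length(step$voltage_samples))
  if (on_idx - 1L < w)
    stop("need at least 100 ms of pre-pulse baseline", call. = FALSE)
  if (step$i_step_pa == 0)
    stop("i_step_pa must be nonzero", call. = FALSE)
  v_base <- mean(step$voltage_samples[(on_idx - w):(on_idx - 1L)])
  v_steady <- mean(step$voltage_samples[(off_idx - w + 1L):off_idx])
  r <- (v_steady - v_base) / step$i_step_pa * 1000  # mV/pA -> MOhm
  structure(
    list(r_input_mohm = r, v_baseline_mv = v_base, v_steady_mv = v_steady,
         i_step_pa = step$i_step_pa, cell_id = step$cell_id),
    class = "passive_props"
  )
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("<passive_props> R_input %.4g MOhm (dV %.4g mV / %g pA)\n",
              x$r_input_mohm, x$v_steady_mv - x$v_baseline_mv, x$i_step_pa))
  invisible(x)
}
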