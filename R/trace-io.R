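#' Sampled membrane current trace with recording metadata
#'
#' The central data container: an ordered vector of current samples in pA
#' (inward-negative convention) plus the metadata the analysis needs (drug
#' application time, cell capacitance, cell/group/condition labels).
#'
#' @param samples Numeric vector of current samples in pA; all finite,
#'   length at least 1.
#' @param sampling_rate_hz Sampling rate in Hz, positive.
#' @param t_drug_s Drug application time in seconds (`NA` if none); must
#'   lie within the recording.
#' @param capacitance_pf Cell capacitance in pF (`NA` if not measured).
#' @param cell_id,group_label,condition Free-text identifiers (e.g. group
#'   "SST" or "PV", condition "SR95531" or "THIP").
#' @param units Unit string; only `"pA"` is accepted — the reader rejects
#'   unit mismatches rather than silently rescaling.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate_hz,
                          t_drug_s = NA_real_, capacitance_pf = NA_real_,
                          cell_id = "", group_label = "", condition = "",
                          units = "pA") {
  if (length(samples) < 1)
    stop("samples must have length >= 1", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  if (length(sampling_rate_hz) != 1 || !is.finite(sampling_rate_hz) ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number", call. = FALSE)
  if (!identical(units, "pA"))
    stop("unsupported units '", units, "': current traces must be in pA",
         call. = FALSE)
  dur <- length(samples) / sampling_rate_hz
  if (!is.na(t_drug_s) && (t_drug_s < 0 || t_drug_s > dur))
    stop("t_drug_s must lie within [0, duration]", call. = FALSE)
  if (!is.na(capacitance_pf) && capacitance_pf <= 0)
    stop("capacitance_pf must be > 0 when given", call. = FALSE)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         t_drug_s = as.numeric(t_drug_s),
         capacitance_pf = as.numeric(capacitance_pf),
         cell_id = as.character(cell_id),
         group_label = as.character(group_label),
         condition = as.character(condition),
         units = "pA", units_checked = TRUE),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s: %d samples at %g Hz (%.6g s)\n",
              if (nzchar(x$cell_id)) x$cell_id else "(unnamed)",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  if (!is.na(x$t_drug_s)) cat(sprintf("  drug at %.6g s\n", x$t_drug_s))
  if (!is.na(x$capacitance_pf))
    cat(sprintf("  capacitance %.6g pF\n", x$capacitance_pf))
  invisible(x)
}

#' Current-clamp step response
#'
#' Voltage trace (mV) around a current step, carrying the pulse window and
#' step amplitude needed by [input_resistance()].
#'
#' @param voltage_samples Numeric voltage samples in mV.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param i_step_pa Injected current step in pA (-10 by the standard
#'   protocol).
#' @param pulse_start_s,pulse_duration_s Pulse window in seconds; the
#'   window must lie inside the trace and last longer than 0.1 s.
#' @param cell_id Cell identifier.
#' @return An object of class `step_response`.
#' @export
step_response <- function(voltage_samples, sampling_rate_hz, i_step_pa,
                          pulse_start_s, pulse_duration_s, cell_id = "") {
  if (length(voltage_samples) < 1 || !all(is.finite(voltage_samples)))
    stop("voltage_samples must be finite and non-empty", call. = FALSE)
  if (sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0", call. = FALSE)
  if (pulse_duration_s <= 0.1)
    stop("pulse_duration_s must exceed 0.1 s (a last-100-ms window is needed)",
         call. = FALSE)
  dur <- length(voltage_samples) / sampling_rate_hz
  if (pulse_start_s < 0 || pulse_start_s + pulse_duration_s > dur)
    stop("pulse window must lie inside the trace", call. = FALSE)
  structure(
    list(voltage_samples = as.numeric(voltage_samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         i_step_pa = as.numeric(i_step_pa),
         pulse_start_s = as.numeric(pulse_start_s),
         pulse_duration_s = as.numeric(pulse_duration_s),
         cell_id = as.character(cell_id)),
    class = "step_response"
  )
}

# header keys written (and accepted) by the text dialect
.trace_header_keys <- c("sampling_rate_hz", "units", "t_drug_s",
                        "capacitance_pf", "cell_id", "group_label",
                        "condition")

#' Write a current trace to the plain-text dialect
#'
#' The text dialect is a UTF-8 file of `#`-prefixed `key=value` header
#' lines (sampling rate, units, drug time, capacitance, labels) followed by
#' one current sample per line in pA; time is implied by index and
#' sampling rate. Files round-trip bit-identically through
#' [read_trace()] at the stated precision.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @param digits Decimal places written for each sample (default 6).
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, digits = 6, overwrite = FALSE) {
  stopifnot(inherits(trace, "current_trace"))
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path, call. = FALSE)
  fmt_num <- function(v) {
    if (is.na(v)) "" else sprintf("%.*f", digits, v)
  }
  hdr <- c(
    sprintf("# sampling_rate_hz=%s",
            format(trace$sampling_rate_hz, scientific = FALSE)),
    "# units=pA",
    if (!is.na(trace$t_drug_s))
      sprintf("# t_drug_s=%s", fmt_num(trace$t_drug_s)),
    if (!is.na(trace$capacitance_pf))
      sprintf("# capacitance_pf=%s", fmt_num(trace$capacitance_pf)),
    if (nzchar(trace$cell_id)) sprintf("# cell_id=%s", trace$cell_id),
    if (nzchar(trace$group_label))
      sprintf("# group_label=%s", trace$group_label),
    if (nzchar(trace$condition)) sprintf("# condition=%s", trace$condition)
  )
  body <- sprintf("%.*f", digits, trace$samples)
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a current trace from the plain-text dialect
#'
#' Counterpart of [write_trace()]. Fails with a named-key error when a
#' required header key is missing, with a unit error when `units` is not
#' `pA`, and with a line-numbered parse error on a non-numeric sample.
#'
#' @param path Path to a trace file in the text dialect.
#' @return A [current_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr_lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2
  if (any(bad))
    stop("malformed header line: '", hdr_lines[bad][1], "'", call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  hdr <- stats::setNames(trimws(vals), trimws(keys))
  for (req in c("sampling_rate_hz", "units")) {
    if (!req %in% names(hdr))
      stop("trace header missing required key '", req, "'", call. = FALSE)
  }
  if (hdr[["units"]] != "pA")
    stop("unsupported units '", hdr[["units"]],
         "': expected pA (no silent rescaling)", call. = FALSE)
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(body_idx) == 0)
    stop("trace file contains no samples", call. = FALSE)
  samples <- suppressWarnings(as.numeric(lines[body_idx]))
  if (anyNA(samples)) {
    first_bad <- body_idx[which(is.na(samples))[1]]
    stop(sprintf("non-numeric sample at line %d: '%s'",
                 first_bad, lines[first_bad]), call. = FALSE)
  }
  get_num <- function(key) {
    if (key %in% names(hdr)) as.numeric(hdr[[key]]) else NA_real_
  }
  get_chr <- function(key) {
    if (key %in% names(hdr)) hdr[[key]] else ""
  }
  current_trace(samples = samples,
                sampling_rate_hz = as.numeric(hdr[["sampling_rate_hz"]]),
                t_drug_s = get_num("t_drug_s"),
                capacitance_pf = get_num("capacitance_pf"),
                cell_id = get_chr("cell_id"),
                group_label = get_chr("group_label"),
                condition = get_chr("condition"))
}

#' Write per-cell results or group comparisons to CSV
#'
#' One row per `tonic_result` (or per `group_comparison`) with a stable
#' column order. A missing capacitance yields an empty current-density
#' cell, never a zero.
#'
#' @param results A list of `tonic_result` objects, a list of
#'   `group_comparison` objects, or a data.frame already in row form.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_results_table <- function(results, path) {
  df <- results_to_df(results)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

# normalize a list of result objects (or a data.frame) to a data.frame
results_to_df <- function(results) {
  if (is.data.frame(results)) return(results)
  stopifnot(is.list(results))
  if (length(results) == 0) {
    return(data.frame(cell_id = character(0), group_label = character(0),
                      condition = character(0), mode = character(0),
                      i_hold_pre_pa = numeric(0), i_hold_post_pa = numeric(0),
                      tonic_shift_pa = numeric(0),
                      tonic_current_pa = numeric(0),
                      current_density_pa_per_pf = numeric(0),
                      capacitance_pf = numeric(0), clean = logical(0)))
  }
  if (inherits(results[[1]], "tonic_result")) {
    do.call(rbind, lapply(results, as.data.frame))
  } else if (inherits(results[[1]], "group_comparison")) {
    do.call(rbind, lapply(results, as.data.frame))
  } else {
    stop("results must be tonic_result or group_comparison objects",
         call. = FALSE)
  }
}
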