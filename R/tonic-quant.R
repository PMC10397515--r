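#' Detect spontaneous synaptic events in a voltage-clamp trace
#'
#' Screens a trace for "obvious" spontaneous IPSCs: the trace is high-pass
#' detrended by subtracting a centered moving-average baseline, the noise
#' scale is estimated robustly (median absolute deviation, so the events
#' themselves do not inflate it), and runs of samples deviating inward
#' (negative) beyond `threshold_sd` robust SDs for at least `min_width_ms`
#' are returned as event intervals.
#'
#' @param trace A [current_trace()] of at least 1 s.
#' @param threshold_sd Detection threshold in robust noise SDs (default 3).
#' @param min_width_ms Minimum excursion width in ms (default 2).
#' @param baseline_window_s Width of the moving-average detrending window
#'   in seconds (default 0.2, slow relative to sIPSC kinetics).
#' @return A data.frame with one row per event interval: `start_index`,
#'   `end_index` (inclusive, 1-based), `start_s`, `end_s`. Zero rows when
#'   no excursion crosses threshold.
#' @export
detect_events <- function(trace, threshold_sd = 3, min_width_ms = 2,
                          baseline_window_s = 0.2) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sampling_rate_hz
  n <- length(trace$samples)
  if (n < fs)
    stop("trace shorter than 1 s: too short for event screening",
         call. = FALSE)
  w <- max(3L, round(baseline_window_s * fs))
  if (w >= n)
    stop("trace shorter than the detrending window", call. = FALSE)
  resid <- trace$samples - moving_average(trace$samples, w)
  sd_rob <- stats::mad(resid)
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      start_s = numeric(0), end_s = numeric(0))
  if (sd_rob == 0) {
    # noiseless constant (or piecewise-smooth) trace: nothing to detect
    return(empty)
  }
  hit <- resid < -threshold_sd * sd_rob
  r <- rle(hit)
  min_w <- max(1L, round(min_width_ms / 1000 * fs))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_w
  if (!any(keep)) return(empty)
  data.frame(start_index = starts[keep], end_index = ends[keep],
             start_s = (starts[keep] - 1L) / fs,
             end_s = (ends[keep] - 1L) / fs)
}

# centered moving average with shrinking windows at the edges; O(n)
moving_average <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Select analysis epochs before and after drug application
#'
#' Picks `n_per_phase` non-overlapping `epoch_len_s`-second segments in
#' each phase (pre-drug, and post-drug starting at least `post_delay_s`
#' after the drug time so the wash-in has approached steady state). Within
#' each phase, segments free of detected events are preferred, earliest
#' first; if fewer than `n_per_phase` event-free windows exist, the least
#' event-contaminated windows are returned instead, flagged
#' `clean = FALSE`, with a warning. Candidate windows are scanned at
#' single-sample resolution and the selection is exact: a dynamic program
#' picks the `n_per_phase` non-overlapping windows minimizing the total
#' number of event-overlapping samples, with ties broken toward the
#' earliest starts. With enough event-free windows this reduces to the
#' earliest eligible non-overlapping windows.
#'
#' @param trace A [current_trace()] with `t_drug_s` set.
#' @param events Event intervals from [detect_events()].
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param n_per_phase Number of epochs per phase (default 3).
#' @param post_delay_s Dead time after the drug before post-phase epochs
#'   may start (default 60 s).
#' @return An `epoch_selection`: a data.frame with columns `start_index`,
#'   `length_samples`, `phase` (`"pre"`/`"post"`), `clean`,
#'   `event_density` (detected event onsets per second), plus attributes
#'   recording the parameters.
#' @export
select_epochs <- function(trace, events, epoch_len_s = 5, n_per_phase = 3,
                          post_delay_s = 60) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.na(trace$t_drug_s))
    stop("select_epochs requires t_drug_s metadata on the trace",
         call. = FALSE)
  fs <- trace$sampling_rate_hz
  n <- length(trace$samples)
  len <- round(epoch_len_s * fs)
  drug_idx <- floor(trace$t_drug_s * fs) + 1L
  post_from <- floor((trace$t_drug_s + post_delay_s) * fs) + 1L

  # per-sample event mask and per-sample event-onset mask
  ev_mask <- integer(n)
  onset_mask <- integer(n)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev_mask[events$start_index[i]:events$end_index[i]] <- 1L
    }
    onset_mask[events$start_index] <- 1L
  }
  cs_ev <- cumsum(c(0, ev_mask))
  cs_on <- cumsum(c(0, onset_mask))

  pick_phase <- function(first, last, phase) {
    n_avail <- last - first + 1L
    if (n_avail < len)
      stop(sprintf("insufficient data in %s-drug phase: %.3g s available, one %g-s epoch needed",
                   phase, max(0, n_avail) / fs, epoch_len_s),
           call. = FALSE)
    if (n_avail < n_per_phase * len)
      stop(sprintf("insufficient data in %s-drug phase: cannot place %d non-overlapping %g-s epochs",
                   phase, n_per_phase, epoch_len_s), call. = FALSE)
    # candidate starts so that [s, s+len-1] lies in [first, last]
    starts <- first:(last - len + 1L)
    ns <- length(starts)
    cost <- cs_ev[starts + len] - cs_ev[starts]
    # DP: B[[j]][i] = minimal total cost of j non-overlapping windows with
    # starts at candidate positions >= i; C[[j]][i] = same but the first
    # window starts exactly at i. Costs are integer sample counts, so the
    # equality test in the traceback is exact.
    revcummin <- function(v) rev(cummin(rev(v)))
    B <- C <- vector("list", n_per_phase)
    C[[1]] <- cost
    B[[1]] <- revcummin(cost)
    if (n_per_phase > 1) {
      for (j in 2:n_per_phase) {
        nxt <- if (ns > len) {
          c(B[[j - 1]][(len + 1):ns], rep(Inf, len))
        } else {
          rep(Inf, ns)
        }
        C[[j]] <- cost + nxt[seq_len(ns)]
        B[[j]] <- revcummin(C[[j]])
      }
    }
    picked <- integer(n_per_phase)
    i <- 1L
    for (j in n_per_phase:1) {
      target <- B[[j]][i]
      p <- i - 1L + which(C[[j]][i:ns] == target)[1]
      picked[n_per_phase - j + 1L] <- starts[p]
      i <- p + len
    }
    data.frame(
      start_index = picked,
      length_samples = len,
      phase = phase,
      clean = (cs_ev[picked + len] - cs_ev[picked]) == 0,
      event_density = (cs_on[picked + len] - cs_on[picked]) / epoch_len_s,
      stringsAsFactors = FALSE
    )
  }

  pre <- pick_phase(1L, min(n, drug_idx - 1L), "pre")
  post <- pick_phase(min(post_from, n), n, "post")
  sel <- rbind(pre, post)
  if (!all(sel$clean))
    warning(sprintf("%d of %d selected epochs contain detected events (clean = FALSE); least-contaminated windows used",
                    sum(!sel$clean), nrow(sel)), call. = FALSE)
  structure(sel, class = c("epoch_selection", "data.frame"),
            epoch_len_s = epoch_len_s, n_per_phase = n_per_phase,
            post_delay_s = post_delay_s)
}

#' All-point histogram of a trace segment
#'
#' Histogram of every sampled current value in a segment, over uniform
#' bins whose edges are aligned to integer multiples of the bin width. The
#' mode reflects the baseline holding current; spontaneous synaptic events
#' populate a skewed tail.
#'
#' @param trace A [current_trace()].
#' @param start_index,length_samples Segment position (1-based start) and
#'   length; defaults cover the whole trace.
#' @param bin_width_pa Bin width in pA (default 0.5).
#' @return An `all_point_histogram`: list with `bin_edges` (length
#'   `nbins + 1`), `counts`, `mode_bin` (index of the maximal count; first
#'   on ties), `n_samples`, `bin_width_pa` and a `degenerate` flag set for
#'   zero-variance segments, which collapse to a single bin.
#' @export
all_point_histogram <- function(trace, start_index = 1L,
                                length_samples = length(trace$samples),
                                bin_width_pa = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  if (bin_width_pa <= 0) stop("bin_width_pa must be > 0", call. = FALSE)
  n <- length(trace$samples)
  if (start_index < 1 || length_samples < 1 ||
      start_index + length_samples - 1L > n)
    stop("segment must lie within the trace", call. = FALSE)
  x <- trace$samples[start_index:(start_index + length_samples - 1L)]
  w <- bin_width_pa
  lo <- floor(min(x) / w)
  hi <- ceiling(max(x) / w)
  if (hi == lo) hi <- lo + 1L  # zero-variance segment: one bin
  edges <- (lo:hi) * w
  # right-open bins [edge_i, edge_{i+1}); top edge closed
  bin <- pmin(length(edges) - 1L, floor(x / w) - lo + 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges, counts = counts,
         mode_bin = which.max(counts), n_samples = length(x),
         bin_width_pa = w,
         degenerate = stats::var(x) == 0),
    class = "all_point_histogram"
  )
}

#' Tail-constrained Gaussian fit of an all-point histogram
#'
#' Fits a Gaussian to the histogram counts while excluding the skewed tail
#' produced by spontaneous synaptic events: with inward (negative) events
#' the fitted window runs from two bins more negative than the peak
#' through the far positive edge, so the peak and two tail-side bins are
#' included and deeper tail bins cannot influence the fit. The fitted mean
#' is the holding-current estimate for the segment.
#'
#' @param hist An [all_point_histogram()].
#' @param tail_side Side of the event tail, `"negative"` (inward events,
#'   default) or `"positive"`.
#' @param peak_offset_bins How many bins beyond the peak toward the tail
#'   remain in the fit (default 2).
#' @param poisson_weights Use `1/max(count, 1)` weights (approximate
#'   Poisson weighting) instead of unweighted least squares.
#' @return A `gaussian_fit`: `mu_pa` (Gaussian mean = holding current),
#'   `sigma_pa`, `amplitude`, `fit_window` (first and last fitted bin
#'   indices), `residual_norm`, `converged`. On optimizer failure the fit
#'   is returned with `converged = FALSE` and `NA` parameters rather than
#'   garbage values.
#' @export
fit_gaussian_constrained <- function(hist,
                                     tail_side = c("negative", "positive"),
                                     peak_offset_bins = 2,
                                     poisson_weights = FALSE) {
  stopifnot(inherits(hist, "all_point_histogram"))
  tail_side <- match.arg(tail_side)
  if (isTRUE(hist$degenerate))
    stop("cannot fit a degenerate (zero-variance) histogram", call. = FALSE)
  nb <- length(hist$counts)
  centers <- (hist$bin_edges[-1] + hist$bin_edges[-(nb + 1)]) / 2
  m <- hist$mode_bin
  if (tail_side == "negative") {
    win <- max(1L, m - as.integer(peak_offset_bins)):nb
  } else {
    win <- 1L:min(nb, m + as.integer(peak_offset_bins))
  }
  if (length(win) < 3)
    stop("fewer than 3 fittable bins: cannot fit Gaussian", call. = FALSE)
  x <- centers[win]
  y <- hist$counts[win]
  amp0 <- hist$counts[m]
  mu0 <- centers[m]
  # sigma start from half width at half maximum around the mode
  above <- which(hist$counts >= amp0 / 2)
  hwhm_bins <- max(1, (max(above) - min(above) + 1) / 2)
  sigma0 <- max(hist$bin_width_pa / 2, hwhm_bins * hist$bin_width_pa / 1.1774)
  wts <- if (poisson_weights) 1 / pmax(y, 1) else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      start = list(a = amp0, mu = mu0, s = sigma0),
      weights = wts,
      lower = c(a = 0, mu = -Inf, s = hist$bin_width_pa / 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(mu_pa = NA_real_, sigma_pa = NA_real_, amplitude = NA_real_,
           fit_window = c(win[1], win[length(win)]),
           residual_norm = NA_real_, converged = FALSE),
      class = "gaussian_fit"))
  }
  co <- stats::coef(fit)
  structure(
    list(mu_pa = unname(co["mu"]), sigma_pa = unname(co["s"]),
         amplitude = unname(co["a"]),
         fit_window = c(win[1], win[length(win)]),
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         converged = is.finite(co["mu"]) && co["s"] > 0),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<gaussian_fit> mu %.3f pA, sigma %.3f pA, amplitude %.1f (bins %d-%d)\n",
                x$mu_pa, x$sigma_pa, x$amplitude,
                x$fit_window[1], x$fit_window[2]))
  } else {
    cat("<gaussian_fit> NOT converged\n")
  }
  invisible(x)
}

#' Holding current of one phase from its selected epochs
#'
#' For each selected segment of the phase, builds the all-point histogram
#' and fits the tail-constrained Gaussian; the fitted peak positions are
#' the per-segment holding currents and their arithmetic mean is the
#' phase's holding current.
#'
#' @param trace A [current_trace()].
#' @param selection An [select_epochs()] result.
#' @param phase `"pre"` or `"post"`.
#' @param bin_width_pa Histogram bin width in pA.
#' @param ... Passed to [fit_gaussian_constrained()] (`tail_side`,
#'   `peak_offset_bins`, `poisson_weights`).
#' @return List with `mean_mu_pa`, `per_segment_mus`, and `fits` (the
#'   `gaussian_fit` objects). A non-converged segment fit is an error
#'   naming the segment.
#' @export
holding_current <- function(trace, selection, phase = c("pre", "post"),
                            bin_width_pa = 0.5, ...) {
  phase <- match.arg(phase)
  seg <- selection[selection$phase == phase, , drop = FALSE]
  if (nrow(seg) == 0)
    stop("selection contains no segments for phase '", phase, "'",
         call. = FALSE)
  fits <- lapply(seq_len(nrow(seg)), function(i) {
    h <- all_point_histogram(trace, seg$start_index[i],
                             seg$length_samples[i], bin_width_pa)
    if (isTRUE(h$degenerate)) {
      # constant segment: the single occupied value is the holding current
      return(structure(
        list(mu_pa = trace$samples[seg$start_index[i]], sigma_pa = 0,
             amplitude = h$n_samples, fit_window = c(1L, 1L),
             residual_norm = 0, converged = TRUE),
        class = "gaussian_fit"))
    }
    fit_gaussian_constrained(h, ...)
  })
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!all(ok))
    stop("Gaussian fit failed to converge for ", phase, " segment(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  mus <- vapply(fits, `[[`, 0, "mu_pa")
  list(mean_mu_pa = mean(mus), per_segment_mus = mus, fits = fits)
}

#' Tonic current from pre- and post-drug holding currents
#'
#' The tonic current is the difference between the holding currents
#' measured before and after drug application: its magnitude is reported
#' as `tonic_current_pa` and the signed change (`post - pre`) is retained
#' as `tonic_shift_pa`. Under an antagonist (e.g. SR95531) the expected
#' shift is outward (positive); under a delta-subunit-preferring agonist
#' (e.g. THIP) it is inward (negative). When the cell capacitance is
#' known, the current density `tonic_current_pa / capacitance_pf` (pA/pF)
#' is also computed.
#'
#' @param i_pre_pa,i_post_pa Holding currents (pA) before and after drug.
#' @param mode `"antagonist"` or `"agonist"` (recorded, not enforced).
#' @param capacitance_pf Cell capacitance in pF, or `NA`.
#' @param cell_id,group_label,condition Metadata carried into the result.
#' @param per_segment_mus Optional list with `pre` and `post` per-segment
#'   holding currents, for diagnostics.
#' @param clean Were all analysis epochs free of detected events?
#' @return A `tonic_result` object.
#' @examples
#' # worked example: SST interneurons under THIP, group-mean holding
#' # currents -56.0 pA before and -99.1 pA after -> 43.1 pA tonic current
#' tonic_current(-56.0, -99.1, mode = "agonist")
#' @export
tonic_current <- function(i_pre_pa, i_post_pa,
                          mode = c("antagonist", "agonist"),
                          capacitance_pf = NA_real_,
                          cell_id = "", group_label = "", condition = "",
                          per_segment_mus = NULL, clean = NA) {
  mode <- match.arg(mode)
  if (!is.finite(i_pre_pa) || !is.finite(i_post_pa))
    stop("holding currents must be finite", call. = FALSE)
  if (!is.na(capacitance_pf) && capacitance_pf <= 0)
    stop("capacitance_pf must be > 0 when given", call. = FALSE)
  shift <- i_post_pa - i_pre_pa
  mag <- abs(shift)
  structure(
    list(cell_id = cell_id, group_label = group_label,
         condition = condition, mode = mode,
         i_hold_pre_pa = i_pre_pa, i_hold_post_pa = i_post_pa,
         tonic_shift_pa = shift, tonic_current_pa = mag,
         current_density_pa_per_pf =
           if (is.na(capacitance_pf)) NA_real_ else mag / capacitance_pf,
         capacitance_pf = capacitance_pf,
         per_segment_mus = per_segment_mus, clean = clean),
    class = "tonic_result"
  )
}

#' @export
print.tonic_result <- function(x, ...) {
  cat(sprintf("<tonic_result> %s%s (%s)\n",
              if (nzchar(x$cell_id)) x$cell_id else "(unnamed)",
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
              x$mode))
  cat(sprintf("  holding current: %.6g -> %.6g pA (shift %+.6g pA)\n",
              x$i_hold_pre_pa, x$i_hold_post_pa, x$tonic_shift_pa))
  cat(sprintf("  tonic current: %.6g pA", x$tonic_current_pa))
  if (!is.na(x$current_density_pa_per_pf))
    cat(sprintf("; density %.6g pA/pF", x$current_density_pa_per_pf))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.tonic_result <- function(x, ...) {
  data.frame(cell_id = x$cell_id, group_label = x$group_label,
             condition = x$condition, mode = x$mode,
             i_hold_pre_pa = x$i_hold_pre_pa,
             i_hold_post_pa = x$i_hold_post_pa,
             tonic_shift_pa = x$tonic_shift_pa,
             tonic_current_pa = x$tonic_current_pa,
             current_density_pa_per_pf = x$current_density_pa_per_pf,
             capacitance_pf = x$capacitance_pf,
             clean = x$clean,
             stringsAsFactors = FALSE)
}

#' Quantify the tonic current of one cell, end to end
#'
#' Full per-cell procedure: detect spontaneous events, select analysis
#' epochs in the pre- and post-drug phases, estimate each phase's holding
#' current from tail-constrained Gaussian fits of the epoch all-point
#' histograms, and take the pre/post difference (normalized by
#' capacitance when available).
#'
#' @param trace A [current_trace()] with `t_drug_s` set.
#' @param mode `"antagonist"` or `"agonist"`.
#' @param threshold_sd,min_width_ms Event-screening parameters
#'   ([detect_events()]).
#' @param epoch_len_s,n_per_phase,post_delay_s Epoch-selection parameters
#'   ([select_epochs()]).
#' @param bin_width_pa Histogram bin width ([all_point_histogram()]).
#' @param ... Passed to [fit_gaussian_constrained()].
#' @return A `tonic_result` with per-segment diagnostics attached.
#' @export
quantify_tonic <- function(trace, mode = c("antagonist", "agonist"),
                           threshold_sd = 3, min_width_ms = 2,
                           epoch_len_s = 5, n_per_phase = 3,
                           post_delay_s = 60, bin_width_pa = 0.5, ...) {
  mode <- match.arg(mode)
  events <- detect_events(trace, threshold_sd = threshold_sd,
                          min_width_ms = min_width_ms)
  sel <- select_epochs(trace, events, epoch_len_s = epoch_len_s,
                       n_per_phase = n_per_phase,
                       post_delay_s = post_delay_s)
  pre <- holding_current(trace, sel, "pre", bin_width_pa = bin_width_pa, ...)
  post <- holding_current(trace, sel, "post", bin_width_pa = bin_width_pa, ...)
  tonic_current(pre$mean_mu_pa, post$mean_mu_pa, mode = mode,
                capacitance_pf = trace$capacitance_pf,
                cell_id = trace$cell_id, group_label = trace$group_label,
                condition = trace$condition,
                per_segment_mus = list(pre = pre$per_segment_mus,
                                       post = post$per_segment_mus),
                clean = all(sel$clean))
}
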