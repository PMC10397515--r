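---
title: "Quantifying tonic GABA-A currents with tail-constrained histogram fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tonic GABA-A currents with tail-constrained histogram fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tonicgaba)
```

## The measurement problem

Extrasynaptic GABA-A receptors carry a sustained ("tonic") chloride
current that does not appear as discrete synaptic events. In a whole-cell
voltage-clamp recording at a fixed holding potential (here −70 mV, high
chloride internal solution, inward currents negative), the tonic current
is visible only as the position of the baseline: block it with an
antagonist such as SR95531 (gabazine) and the holding current steps
outward; engage δ-subunit-containing receptors with the agonist THIP
(gaboxadol) and it steps inward. The quantity of interest is therefore
the difference between the holding currents measured before and after the
drug, optionally divided by the cell capacitance to give a current
density in pA/pF that normalizes for cell size.

The obstacle is that the same recording is riddled with spontaneous
inhibitory postsynaptic currents (sIPSCs): transient inward deflections
with fast rise and slower decay. A naive segment mean is pulled inward by
every event; an estimator of the baseline must see past them.

## The estimator

`quantify_tonic()` implements the field's standard all-point-histogram
procedure per cell:

1. **Event screening** (`detect_events()`). The trace is detrended with a
   centered moving average (200 ms window, slow relative to sIPSC
   kinetics), the noise scale is estimated with the median absolute
   deviation so the events themselves cannot inflate it, and inward
   excursions beyond 3 robust SDs lasting at least 2 ms are flagged.
   "Obvious event" has no quantitative definition in common practice;
   both knobs are exposed and echoed into the run report.
2. **Epoch selection** (`select_epochs()`). Three non-overlapping 5-s
   epochs are chosen in each phase: before the drug, and after it with a
   dead time (`post_delay_s`) that lets the drug wash in. Windows free of
   detected events are preferred, earliest first. When no clean windows
   exist — the usual situation at physiological sIPSC rates — an exact
   dynamic program returns the set of non-overlapping windows minimizing
   the total number of event-contaminated samples (ties toward the
   earliest start), flags them `clean = FALSE`, and warns. Selection is
   deterministic by construction.
3. **All-point histogram** (`all_point_histogram()`). Every sample of an
   epoch is binned at 0.5 pA with edges aligned to multiples of the bin
   width. The mode tracks the baseline; the sIPSCs form a skewed inward
   tail. A 5-s epoch at 10 kHz contributes 50,000 samples, i.e. roughly
   500 counts in a central bin — enough for a stable fit while 0.5 pA
   still resolves few-pA shifts.
4. **Tail-constrained Gaussian fit** (`fit_gaussian_constrained()`). A
   Gaussian is least-squares fitted to the counts over a window running
   from two bins beyond the peak on the event-tail side through the far
   edge of the opposite side. The peak and two tail-side bins anchor the
   fit; deeper tail bins — the sIPSC mass — are excluded so they cannot
   drag the fitted mean inward. The fitted mean is the epoch's holding
   current. Starting values come from the mode (mean), the mode count
   (amplitude) and the half-width at half-maximum (SD); optimizer failure
   returns `converged = FALSE` rather than numbers.
5. **Tonic current** (`tonic_current()`). Each phase's holding current is
   the arithmetic mean of its three fitted epoch means; the tonic current
   is the magnitude of the pre/post difference (the signed shift is
   retained), and the density is the magnitude divided by capacitance.

### The side of the excluded tail

With inward-negative currents, sIPSCs are *larger in magnitude* but *more
negative in value*, so "higher-amplitude" event values sit on the
negative side of the histogram. The fit window therefore keeps the peak
plus `peak_offset_bins = 2` bins toward the negative side and excludes
everything more negative, while keeping the whole positive flank. Both
the side (`tail_side`) and the offset are configurable; recordings
digitized with the opposite polarity can set `tail_side = "positive"`
without re-signing their data.

### Sign conventions

Inward currents are negative everywhere in the package. Antagonist block
of a standing tonic current produces a positive (outward) shift; agonist
induction produces a negative (inward) shift. Reported tonic currents are
magnitudes with the signed shift kept alongside, so summaries remain
comparable across the two experiment designs without a sign convention
fight.

## The synthetic recording model

`simulate_trace()` generates the ground-truth data every validation rests
on:

* stationary holding current `i_hold_pa` plus Gaussian recording noise
  (`noise_sd_pa`, default 3 pA before filtering), low-pass filtered at
  `filter_cutoff_hz` (default 4 kHz, emulating the acquisition Bessel
  filter) — implemented as the squared-magnitude response of a
  second-order Butterworth applied in the frequency domain, which is
  zero-phase and fast; the filter family is a documented choice, not a
  claim about any particular amplifier;
* sIPSCs arriving as a Poisson process (`event_rate_hz`, default 2 Hz),
  each a difference-of-exponentials kernel (τ_rise 1 ms, τ_decay 10 ms —
  typical GABA-A kinetics in order of magnitude) normalized so its peak
  equals an amplitude drawn lognormal (mean 30 pA, CV 0.5: strictly
  positive and right-skewed, as real sIPSC amplitude distributions are),
  applied inward;
* a drug-induced sustained shift `tonic_shift_pa` that washes in as a
  single exponential (`washin_tau_s`, default 30 s) from `t_drug_s`, with
  the event rate multiplied by `post_drug_event_scale` afterwards (0 for
  an antagonist that abolishes sIPSCs, 1 for an agonist that leaves them
  untouched).

`simulate_cohort()` adds independent Gaussian between-cell jitter to any
subset of these parameters and derives one sub-seed per cell from a
master seed, emulating a recorded group. `simulate_step_response()`
produces a single-compartment RC voltage response to a current step for
validating `input_resistance()` (baseline = 100 ms before onset, steady
state = last 100 ms of the 1-s pulse, R = ΔV/ΔI, where 1 mV/1 pA =
1000 MΩ).

The sIPSC rate, amplitude and kinetics defaults are plausible values for
hippocampal interneurons, not estimates fitted to any particular cell
type: no public raw recordings back them. What the generator does *not*
contain is equally important for reading the tests: no series-resistance
or seal drift, no slow baseline wander, no voltage-gated conductances,
no event-kinetics variability, and recording noise that is Gaussian by
construction. Passing validation therefore demonstrates that the
estimator recovers known baselines under Poisson event contamination and
stationary Gaussian noise — not that it is immune to rundown or seal
instability, which no baseline-difference method is.

## Numerical and design choices

* **Bin width 0.5 pA** balances resolution against per-bin counts (see
  above); it is exposed as `bin_width_pa`.
* **Unweighted least squares** on counts is the default; approximate
  Poisson weighting (`poisson_weights = TRUE`) is available. The fitted
  peak and the segment mean are different estimators of the same
  baseline, and their difference fluctuates on the same σ/√N scale as
  either one; the test suite asserts agreement at a small multiple of
  that scale plus unbiasedness across seeds, not pointwise equality.
* **Degenerate epochs** (zero variance, e.g. noiseless synthetic traces)
  collapse to a single histogram bin; the fit layer refuses them and the
  holding-current layer short-circuits to the exact constant value.
* **Wash-in vs analysis delay.** With the default wash-in τ of 30 s, a
  60-s `post_delay_s` leaves the shift ~86% complete at the first post
  epoch — acceptable for screening, but a biased validation target. The
  validation studies in the tests and the acceptance script therefore
  record 160 s with the drug at 20 s and set `post_delay_s = 120`
  (≥ 98% complete), which mirrors how an experimenter waits for a stable
  post-drug baseline before reading it. The package default stays at
  60 s; it is a screening default, echoed in every run report.
* **Epoch fallback as exact optimization.** Greedy minimum-density
  picking can wedge itself: its first pick may straddle the only packing
  of three windows into a tight phase. The dynamic program is linear in
  trace length per epoch and cannot fail when the phase is long enough.
* **Exact Mann–Whitney p-values** come from the null-distribution
  counting recursion `c(u; n1, n2) = c(u − n2; n1−1, n2) + c(u; n1,
  n2−1)`, with the classical two-sided rule — twice the smaller tail
  including the observed point mass, capped at 1. This rule reproduces
  published exact tables; the test suite cross-checks it against full
  enumeration (all group sizes with n1+n2 ≤ 12) and against
  `stats::wilcox.test(exact = TRUE)`. The exact path applies to tie-free
  data with n1+n2 ≤ 30; ties get mid-ranks and a seeded permutation
  p-value (10^5 permutations by default), labelled as such — discrete
  measurements should not silently borrow a continuous null.
* **Determinism.** Every stochastic component takes an explicit seed and
  runs under `withr::with_seed`, so a run configuration plus seed
  reproduces every output file byte for byte; the run report records all
  parameters, defaults included, and omits wall-clock information for
  exactly that reason.

## Validation studies (sizes and rationale)

The acceptance script (`scripts/acceptance.R`) and the acceptance test
file recompute, from scratch at a caller-supplied seed:

* exact p-values for the three published (U, n1, n2) triples of the
  motivating comparisons — (6, 7, 7), (7, 7, 7), (6, 8, 5);
* the worked agonist example: holding currents −56.0 → −99.1 pA give a
  43.1 pA tonic current;
* end-to-end recovery of tonic shifts of 5, 9.1, 22.5, 43.1 and 89.7 pA
  (the span of published group means), 50 seeds per level, 160-s
  recordings at default noise and event settings, tolerance
  max(2 pA, 10%);
* the contamination-robustness comparison: at sIPSC rates 1–5 Hz
  (40 seeds each), the constrained fit must beat the naive segment mean
  in ≥ 95% of paired seeds — this property is the reason the procedure
  exists;
* conservatism of the exact test under the null (10^4 simulated 7-vs-7
  datasets, rejection rate ≤ 0.05 at α = 0.05);
* input-resistance recovery of a 150 MΩ cell (τ = 20 ms, 0.2 mV noise,
  100 seeds, mean within 2%).

A 14-cell demonstration cohort (`inst/extdata/demo_run.yaml`: 22.5 vs
9.1 pA group-level shifts, dispersions on the SEM·√n scale of the
motivating data, antagonist mode with events abolished post-drug) runs
twice to verify byte-identical outputs and once to check that the group
difference comes out significant.

## Limitations

* The estimator assumes the baseline is stationary within each phase;
  slow drift biases any pre/post difference and is neither simulated nor
  corrected.
* Cell capacitance is metadata (as read from an amplifier), not
  estimated from the capacitive transient.
* The event screen is a detection heuristic for *selecting* epochs, not
  an sIPSC analysis; amplitudes, frequencies and kinetics of events are
  out of scope.
* The exact U recursion assumes no ties; the permutation fallback is
  honest but Monte-Carlo.
* Proprietary acquisition formats (e.g. ABF) are not read; traces enter
  through the plain-text dialect of `read_trace()`/`write_trace()`.
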