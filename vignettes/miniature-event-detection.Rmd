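---
title: "Detecting and measuring miniature synaptic events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring miniature synaptic events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minidetect)
```

## The problem

Miniature postsynaptic events (mEPSCs, mEJCs, and their current-clamp
counterparts) are small, fast, stochastic deflections in an
electrophysiological recording. Quantifying them — how many, how large, how
fast they rise and decay — is a routine but error-prone step in studies of
synaptic function and plasticity. `minidetect` provides a headless,
scriptable implementation of a template-free detection algorithm for such
events, a synthetic-recording simulator with analytic ground truth for
validating it, and the surrounding preprocessing utilities (filtering,
baseline subtraction, sweep averaging, evoked-response summaries).

## The detection algorithm

Detection operates on one sweep at a time and consists of five stages.

**1. Candidate search.** The sweep is scanned in a series of windows of
width `auto_diameter_ms` (default 20 ms), each shifted by half the diameter,
so every sample is interior to at least one window. The global extremum of
each window (maximum for positive-going events, minimum for negative-going)
is a candidate peak. An extremum sitting on a window's first or last sample
is deferred to the overlapping window in which it is interior — on a
monotone stretch of trace the extremum is always at a window edge, so pure
rises, decays and flat segments generate no candidates. Duplicate candidates
from overlapping windows are processed once. In manual mode
(`find_event_manual()`) a single window of half-width `search_radius_ms`
around a user-supplied time is searched instead, and the result is reported
whether accepted or rejected, so a puzzling stretch of trace can be
interrogated.

**2. Onset and baseline.** From the candidate peak the algorithm walks
backward, comparing each sample with the mean of the `ma_window` preceding
samples. The first visited sample that is *not* strictly on the event's side
of that moving average is the last pre-event point; the next sample is the
onset, and the moving-average value there is the baseline. Two details
matter:

* *Tie handling.* A sample exactly equal to the moving average stops the
  scan. On an exactly flat baseline the scan therefore stops at the event
  foot rather than running to the start of the sweep; on real (noisy) data
  equality has probability zero and the rule is equivalent to the strict
  crossing. A related numerical point: the moving average is computed from
  cumulative-sum differences, not a rolling update, because the rolling
  update's floating-point residue makes the average over an exactly flat
  stretch slightly nonzero and defeats the tie rule.
* *Detached baseline window.* When the trace immediately before the onset is
  corrupted — the canonical case is mains hum — `baseline_mode =
  "fixed_left_window"` instead uses the mean of a window of width
  `fixed_window_ms` ending `fixed_offset_ms` before the peak. Placing the
  window's center one hum period before the peak samples the hum at the same
  phase as the peak, so the hum cancels out of the amplitude. The defaults
  (offset 17.5 ms, width 5 ms) center the window 20 ms before the peak, one
  period of 50 Hz hum.

A caveat on drifting baselines: on a monotone drift the trace is above the
moving average of its predecessors everywhere, so the crossing is found only
where noise carries the trace below the local mean; onset error on drifting
data is of order noise amplitude divided by drift slope, typically a
fraction of a millisecond, not a single sample.

**3. Measurement.** Amplitude is the difference between the peak sample and
the baseline, signed along the detection direction. The 10–90% rise time is
the time between the latest 10% and 90% amplitude crossings before the peak,
and the half-width is the time between the 50% crossing on the rise and the
first 50% crossing after the peak; all crossings are linearly interpolated
between samples. All measures are invariant to adding a constant to the
trace, and detection on a negated trace with the direction flipped yields
identical events with negated baselines.

**4. Decay.** A single exponential `B * exp(-t / tau)` is fitted to the
baseline-subtracted trace from the peak forward by nonlinear least squares
(`decay_method = "lm_fit"`), starting from `B` = amplitude and `tau` = the
interpolated 1/e crossing time. A single exponential is the standard model
for synaptic decay and keeps "the" decay constant well defined. The fit span
runs to the smallest of `decay_fit_max_ms` (by default five times the 1/e
estimate, else 50 ms), the next detected event's onset, and the sweep end.
The baseline is *not* a free parameter — this keeps the arithmetic of
compound-event subtraction (below) exact. `decay_method = "one_over_e"` is a
curve-agnostic alternative: the time from the peak to the earliest 1/e
amplitude crossing, which equals the fitted constant on true
single-exponential data. For events with a rounded (double-exponential)
shape the fitted constant is a model-mismatched summary; validation
therefore compares it against the analytic 1/e time of the true curve via
correlation, not equality.

**5. Compound resolution and filters.** Two candidate peaks closer than
`min_peak_separation_ms` are split into separate events only if some sample
between them comes closer to the earlier event's baseline than
`valley_percent` of the earlier amplitude. If a valley exists, the later
event's onset is the between-peak sample of minimum amplitude, and its
baseline at every sample is the earlier baseline plus the earlier event's
fitted decay extrapolated forward — amplitudes of overlapping events are
measured from the level to which the predecessor has decayed, not from the
original baseline (events are assumed to sum). If no valley exists the later
extremum is discarded as part of the earlier event's decay. Finally,
acceptance filters are checked in the fixed order amplitude → rise →
half-width → decay constant; the first violated bound rejects the event with
that criterion's name, and an undefined measurement fails any bound set on
it. Rejected events are retained in the output with their reason, so a
headless run preserves the transparency of interactive accept/reject
workflows.

*Ordering note.* Because the filter chain short-circuits at the amplitude
check, a candidate that fails the amplitude bounds is rejected before any
kinetics are computed and never counts as a detected event: it neither
anchors compound resolution nor truncates a neighbour's decay-fit span. This
matters in practice — noise ripples on a decay would otherwise cut decay
fits short and destroy the accuracy of the fitted constants.

## The simulator

`build_recording()` concatenates `[spacer, event]` segments on a zero
baseline at 10 kHz (`dt_ms = 0.1`). Spacer lengths are uniform random
integers in 100–500 samples (10–50 ms). Two event shapes are available:

* **biexp** — `A' * (1 - exp(-t/tau1)) * exp(-t/tau2)`, a rounded shape
  resembling potential data, with `tau1 ~ U(2, 10)` ms and
  `tau2 ~ U(2, 15)` ms. The prefactor is rescaled after drawing the time
  constants so that the curve maximum equals a target amplitude
  `~ U(0.5, 2.5)`, using the closed-form peak time
  `t* = tau1 * log(1 + tau2/tau1)`. Each waveform is evaluated out to
  `5 * (tau1 + tau2)`, which guarantees decay below 1% of the peak before
  the next spacer begins. Under these ranges the implied peak offsets span
  about 1.4–9.2 ms and the 1/e decay times about 3.2–21.9 ms; the tails
  below 1.9 ms (~2.6%) and below 4.75 ms (~6%) are a property of the stated
  uniform ranges, and the generator does not reject them.
* **sharp** — a linear rise to `A` over `t_rise` followed by
  `A * exp(-(t - t_rise)/tau_decay)`, resembling voltage-clamp current
  data. The true 10–90% rise time is `0.8 * t_rise` and the true 1/e time
  is `tau_decay` exactly. No canonical parameter ranges exist for this
  shape, so the sampler defaults to `t_rise ~ U(0.5, 3)` ms (typical
  voltage-clamp rise times) and `tau_decay ~ U(5, 25)` ms (the range used
  by the hum stress test).

Ground-truth kinetics are always computed from the analytic curve by
bisection to 1e-9 ms (`true_kinetics()`), never from the shape parameters,
because for the biexp both time constants influence both the rise time and
the 1/e time.

Three noise generators emulate recording artifacts:

* `add_sine_noise()` — deterministic ripple, default amplitude 0.02 with a
  1 ms period; useful because it bounds the displacement of every feature.
* `add_correlated_noise()` — one Gaussian deviate per sample
  (`sd = 0.02/5` by default), each output sample receiving the sum of the
  deviates in a centered 11-point window. The summed noise has interior
  standard deviation `sqrt(11) * sd` and lag-k autocorrelation
  `(11 - k)/11`, mimicking amplifier drift better than white noise. At the
  sweep edges the sum is truncated to existing samples (at most 5 samples
  per edge are affected; no padding is invented).
* `add_hum()` — mains interference, default 0.2 amplitude with a 20 ms
  period (50 Hz). For the hum stress test the Gaussian scale is set by
  `hum_noise_sd()`: `3 * sqrt(11) * sd = 0.1`, i.e. typical summed-noise
  excursions of ±0.1, which together with the 0.4 peak-to-peak hum gives
  the ~0.6 peak-to-peak event-free noise band the stress test assumes.

What the simulator does **not** model: amplifier/filter transfer functions,
Poisson event timing, overlapping events (spacing guarantees full decay;
compound tests build summed traces explicitly), capacitive artifacts, and
seal instability. A green benchmark therefore establishes correctness of the
measurement pipeline under the stated noise models, not performance on any
particular preparation.

## The validation harness

`run_benchmark()` builds a scenario's recording, runs `scan_auto()`, matches
accepted detections to ground truth greedily by nearest peak time, and
reports squared Pearson correlations between true and estimated onset time,
amplitude, 10–90% rise and decay constant, plus miss and false-positive
counts. Counts are conserved (`n_true = n_matched + n_missed`,
`n_detected = n_matched + n_false_positive`) and runs are bit-reproducible
under a fixed seed.

The default match tolerance is 2 ms — far below the minimum ~10 ms
inter-event spacing. The hum scenario uses 15 ms: hum can carry the apparent
maximum of a small, slowly decaying event toward the next hum crest (the
displaced crest wins whenever `A * exp(-t/tau) + 0.2` exceeds the trace
value at the true peak, which happens for events near hum troughs with
`A/tau` below the maximal hum slope), so displacements approaching one hum
period are physical; 15 ms still sits below half the minimum ~35 ms peak
spacing of that scenario, so matching stays unambiguous.

Benchmark detection parameters are deliberately plain: moving-average
baseline with `ma_window = 100` samples (10 ms), 20 ms scan windows, and a
minimum amplitude of 0.3 — below the smallest true amplitude (0.5) and above
the noise. The hum scenario instead uses the detached baseline window
centered one hum period before the peak and a minimum amplitude of 0.45.
That threshold is placed between the largest response the hum + noise can
produce through the measurement path (~0.44: a hum crest riding the tail of
an earlier event, measured via compound subtraction against the earlier
event's phase-mismatched baseline) and the smallest true event (0.5) — the
general rule being that an amplitude cutoff belongs between the noise
response and the event amplitudes. Compound resolution stays enabled there:
it is what discards secondary noise extrema on an event's own decay.

## Numerical choices

* Time windows are half-open `[start, end)`; indices are 1-based in R
  convention. A sample exactly at a window's end belongs to the next window,
  so scan seams never double-count.
* Crossing times (10/50/90%, 1/e) are linearly interpolated; rise uses the
  *latest* crossings before the peak, half-width decay the *first* crossing
  after, which makes the measures robust to ripple re-crossings.
* The decay fit uses `stats::nls` (port algorithm, bounded below by
  `tau > dt/10`); non-convergence yields an undefined constant, which any
  set decay filter then rejects. A brute-force profiled grid search over
  `tau` serves as the independent oracle in the tests, agreeing to <1%.
* The Bessel low-pass is designed from first principles (reverse Bessel
  polynomial poles, magnitude-normalized so the -3 dB point sits at the
  requested cutoff, bilinear transform with prewarping) and applied
  forward-backward. Zero-phase filtering is the right choice upstream of
  onset/rise measurements — a causal pass would delay onsets by the filter's
  group delay — at the cost of squaring the magnitude response (the
  effective order doubles). DC gain is exactly 1 by construction.
* Boxcar filtering uses reflected padding so output length equals input
  length and flat baselines are preserved exactly at the edges.
* Evoked summaries use the sample (N−1) standard deviation; a single sweep
  reports 0 with a flag rather than NA.

## Known limitations

* Multi-exponential decays are summarized by a single constant by design.
* The ABF reader covers the version-1 binary layout (float and scaled
  16-bit integer data, one channel materialized per call); ABF2 files are
  rejected with a clear error, and ABF writing is not supported.
* Sweeps are scanned independently; events straddling a sweep boundary are
  not stitched.
* The compound baseline extrapolates the earlier event's *fitted* decay; on
  data where that fit is poor (heavy hum, non-exponential decays) later
  amplitudes inherit its error, and under hum the compound path can promote
  a crest near a real event unless the amplitude cutoff excludes it (see
  above).
* The moving-average onset rule assumes the pre-event baseline is locally
  stationary; on steady drifts the onset lands within the noise/slope
  scale, not within one sample.
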