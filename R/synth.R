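# Synthetic mock recordings with analytic ground truth.
#
# Two event shapes are available: a product of a rising and a decaying
# exponential ("biexp", rounded peak, resembling potential data),
#
#   y(t) = A' (1 - exp(-t/tau1)) exp(-t/tau2),
#
# and a "sharp" piecewise shape (linear rise to A over t_rise, then a single
# exponential decay with constant tau_decay) resembling voltage-clamp
# current data. Ground-truth kinetics (10-90% rise time, 1/e decay time) are
# always computed from the analytic curve, not from the shape parameters,
# because for the biexp both time constants influence both quantities.

#' Closed-form peak time of the biexp event shape
#'
#' The curve `(1 - exp(-t/tau1)) * exp(-t/tau2)` attains its maximum at
#' `t = tau1 * log(1 + tau2/tau1)`.
#'
#' @param tau1,tau2 Rise and decay time constants (ms).
#' @return Peak time in ms from event onset.
#' @export
biexp_peak_time <- function(tau1, tau2) tau1 * log(1 + tau2 / tau1)

.biexp_unit <- function(t, tau1, tau2) (1 - exp(-t / tau1)) * exp(-t / tau2)

.biexp_unit_max <- function(tau1, tau2) {
  u <- tau1 / (tau1 + tau2)          # exp(-t*/tau1) at the peak
  (1 - u) * u^(tau1 / tau2)
}

#' True 10-90% rise time and 1/e decay time of an analytic event curve
#'
#' Both quantities are measured on the curve itself by root bisection
#' ([stats::uniroot()] to 1e-9 ms): the rise time is the time between the
#' 10% and 90% amplitude crossings on the rising limb, and the 1/e decay
#' time is the first time after the peak at which the curve has fallen to
#' `amplitude/e`.
#'
#' @param f Vectorized function of time (ms) evaluating the event curve.
#' @param peak_time Time of the curve maximum (ms).
#' @param amplitude Curve value at the peak.
#' @param t_end Upper bracket for the decay search (ms after the peak).
#' @return A list with `rise_10_90_ms` and `tau_1e_ms`.
#' @export
true_kinetics <- function(f, peak_time, amplitude, t_end = 100 * peak_time + 1000) {
  cross <- function(level, lo, hi) {
    stats::uniroot(function(t) f(t) - level, lower = lo, upper = hi,
                   tol = 1e-9)$root
  }
  eps <- 1e-12
  t10 <- cross(0.1 * amplitude, eps, peak_time)
  t90 <- cross(0.9 * amplitude, t10, peak_time)
  t1e <- cross(amplitude / exp(1), peak_time, peak_time + t_end)
  list(rise_10_90_ms = t90 - t10, tau_1e_ms = t1e - peak_time)
}

#' Evaluate a biexp event waveform with ground truth
#'
#' The internal scale factor is chosen after the fact so that the curve
#' maximum equals `amplitude` exactly (the raw maximum depends on both time
#' constants, not just the prefactor). Samples are taken at
#' `t = 0, dt, ..., < t_max` with `t_max = 5 * (tau1 + tau2)`, which
#' guarantees decay below 1% of the peak before the waveform ends.
#'
#' @param tau1,tau2 Rise/decay time constants in ms (`2 < tau1 < 10`,
#'   `2 < tau2 < 15` under the default sampler).
#' @param amplitude Target peak height in signal units.
#' @param dt_ms Sampling interval in ms.
#' @param t_max_ms Evaluation length in ms (default `5 * (tau1 + tau2)`).
#' @return A list with `samples`, `peak_time_ms` (from waveform start),
#'   `amplitude`, `rise_10_90_ms`, `tau_1e_ms`, and `curve`, the analytic
#'   evaluator (function of t in ms).
#' @export
biexp_waveform <- function(tau1, tau2, amplitude, dt_ms = 0.1,
                           t_max_ms = 5 * (tau1 + tau2)) {
  stopifnot(tau1 > 0, tau2 > 0, amplitude > 0, dt_ms > 0)
  scale <- amplitude / .biexp_unit_max(tau1, tau2)
  f <- function(t) scale * .biexp_unit(t, tau1, tau2)
  n <- ceiling(t_max_ms / dt_ms)
  t <- (seq_len(n) - 1) * dt_ms
  tp <- biexp_peak_time(tau1, tau2)
  kin <- true_kinetics(f, tp, amplitude, t_end = 20 * tau2 + 100)
  list(samples = f(t), peak_time_ms = tp, amplitude = amplitude,
       rise_10_90_ms = kin$rise_10_90_ms, tau_1e_ms = kin$tau_1e_ms,
       curve = f)
}

#' Evaluate a sharp (linear rise, exponential decay) event waveform
#'
#' `y(t) = A t / t_rise` for `t <= t_rise`, then
#' `y(t) = A exp(-(t - t_rise)/tau_decay)`. The true 10-90% rise time is
#' `0.8 * t_rise` and the true 1/e decay time is `tau_decay`. The waveform
#' is evaluated out to `t_rise + 5 * tau_decay`.
#'
#' @param t_rise Full rise time in ms.
#' @param amplitude Peak height `A` in signal units.
#' @param tau_decay Decay time constant in ms.
#' @param dt_ms Sampling interval in ms.
#' @return Same structure as [biexp_waveform()].
#' @export
sharp_waveform <- function(t_rise, amplitude, tau_decay, dt_ms = 0.1) {
  stopifnot(t_rise > 0, amplitude > 0, tau_decay > 0, dt_ms > 0)
  f <- function(t) ifelse(t <= t_rise, amplitude * t / t_rise,
                          amplitude * exp(-(t - t_rise) / tau_decay))
  n <- ceiling((t_rise + 5 * tau_decay) / dt_ms)
  t <- (seq_len(n) - 1) * dt_ms
  list(samples = f(t), peak_time_ms = t_rise, amplitude = amplitude,
       rise_10_90_ms = 0.8 * t_rise, tau_1e_ms = tau_decay, curve = f)
}

#' Default event-parameter samplers
#'
#' `sample_biexp_specs()` draws `tau1 ~ U(2, 10)` ms, `tau2 ~ U(2, 15)` ms
#' and target amplitude `~ U(0.5, 2.5)` signal units. `sample_sharp_specs()`
#' draws `t_rise ~ U(0.5, 3)` ms, `tau_decay ~ U(5, 25)` ms and amplitude
#' `~ U(0.5, 2.5)`. Both consume the R random number stream.
#'
#' @param n Number of event specs to draw.
#' @param tau1_range,tau2_range,t_rise_range,tau_decay_range,amplitude_range
#'   Uniform ranges for each parameter.
#' @return A data.frame with a `shape` column (`"biexp"` or `"sharp"`) and
#'   the shape parameters (`NA` where not applicable).
#' @export
sample_biexp_specs <- function(n, tau1_range = c(2, 10), tau2_range = c(2, 15),
                               amplitude_range = c(0.5, 2.5)) {
  data.frame(
    shape = "biexp",
    tau1 = stats::runif(n, tau1_range[1], tau1_range[2]),
    tau2 = stats::runif(n, tau2_range[1], tau2_range[2]),
    t_rise = NA_real_, tau_decay = NA_real_,
    amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]))
}

#' @rdname sample_biexp_specs
#' @export
sample_sharp_specs <- function(n, t_rise_range = c(0.5, 3),
                               tau_decay_range = c(5, 25),
                               amplitude_range = c(0.5, 2.5)) {
  data.frame(
    shape = "sharp",
    tau1 = NA_real_, tau2 = NA_real_,
    t_rise = stats::runif(n, t_rise_range[1], t_rise_range[2]),
    tau_decay = stats::runif(n, tau_decay_range[1], tau_decay_range[2]),
    amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]))
}

.waveform_from_spec <- function(spec, dt_ms) {
  if (spec$shape == "biexp") {
    biexp_waveform(spec$tau1, spec$tau2, spec$amplitude, dt_ms)
  } else {
    sharp_waveform(spec$t_rise, spec$amplitude, spec$tau_decay, dt_ms)
  }
}

#' Build a mock recording with known ground truth
#'
#' Concatenates `[spacer, event]` segments on a zero baseline. Spacer
#' lengths are uniformly distributed integers in `spacing_range` samples
#' (default 100-500 samples, i.e. 10-50 ms at the default 10 kHz sampling
#' rate). Event parameters are drawn by `event_sampler`. The result is
#' noise-free; add noise with [add_sine_noise()], [add_correlated_noise()]
#' and/or [add_hum()].
#'
#' @param n_events Number of events (>= 1).
#' @param event_sampler Function `n -> data.frame` of event specs, as
#'   returned by [sample_biexp_specs()] or [sample_sharp_specs()].
#' @param spacing_range Integer range of spacer lengths in samples.
#' @param dt_ms Sampling interval in ms (default 0.1, i.e. 10 kHz, so the
#'   default spacing of 100-500 samples spans 10-50 ms).
#' @param seed Optional integer seed; when given, the recording and truth
#'   table are bit-reproducible.
#' @param unit_label Unit label for the recording.
#' @return A list with `recording` (a [recording()]) and `truth`, a
#'   data.frame with columns `onset_time_s`, `peak_time_s`, `amplitude`,
#'   `rise_10_90_ms`, `tau_1e_ms`, `shape`, `tau1`, `tau2`, `t_rise`,
#'   `tau_decay`, sorted by onset time.
#' @export
build_recording <- function(n_events, event_sampler = sample_biexp_specs,
                            spacing_range = c(100L, 500L), dt_ms = 0.1,
                            seed = NULL, unit_label = "nA") {
  if (n_events < 1L) stop("'n_events' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  specs <- event_sampler(n_events)
  spacers <- if (spacing_range[1] == spacing_range[2]) {
    rep.int(as.integer(spacing_range[1]), n_events)
  } else {
    sample.int(spacing_range[2] - spacing_range[1] + 1L, n_events,
               replace = TRUE) + as.integer(spacing_range[1]) - 1L
  }
  segs <- vector("list", 2L * n_events)
  truth <- specs
  truth$onset_time_s <- NA_real_
  truth$peak_time_s <- NA_real_
  truth$rise_10_90_ms <- NA_real_
  truth$tau_1e_ms <- NA_real_
  pos <- 0L  # samples emitted so far
  for (k in seq_len(n_events)) {
    wf <- .waveform_from_spec(specs[k, ], dt_ms)
    segs[[2L * k - 1L]] <- numeric(spacers[k])
    segs[[2L * k]] <- wf$samples
    onset_samples <- pos + spacers[k]          # 0-based index of first event sample
    truth$onset_time_s[k] <- onset_samples * dt_ms * 1e-3
    truth$peak_time_s[k] <- truth$onset_time_s[k] + wf$peak_time_ms * 1e-3
    truth$rise_10_90_ms[k] <- wf$rise_10_90_ms
    truth$tau_1e_ms[k] <- wf$tau_1e_ms
    pos <- onset_samples + length(wf$samples)
  }
  trace <- unlist(segs, use.names = FALSE)
  truth <- truth[order(truth$onset_time_s),
                 c("onset_time_s", "peak_time_s", "amplitude",
                   "rise_10_90_ms", "tau_1e_ms", "shape",
                   "tau1", "tau2", "t_rise", "tau_decay")]
  rownames(truth) <- NULL
  list(recording = recording(trace, dt = dt_ms * 1e-3, unit_label = unit_label),
       truth = truth)
}

#' Add sinusoidal noise to a recording
#'
#' Adds `amplitude * sin(2 * pi * t / period_ms)` (t in ms) to every sweep.
#' The default emulates fine-grained measurement ripple: amplitude 0.02
#' signal units with a 1 ms period.
#'
#' @param rec A [recording()].
#' @param amplitude Sine amplitude in signal units (>= 0).
#' @param period_ms Sine period in ms.
#' @return The recording with noise added.
#' @export
add_sine_noise <- function(rec, amplitude = 0.02, period_ms = 1) {
  stopifnot(inherits(rec, "recording"), amplitude >= 0, period_ms > 0)
  t_ms <- rec_times(rec) * 1e3
  term <- amplitude * sin(2 * pi * t_ms / period_ms)
  rec$sweeps <- lapply(rec$sweeps, function(x) x + term)
  rec
}

#' Add mains-hum interference to a recording
#'
#' A 50 Hz mains hum has a 20 ms period; the default amplitude of 0.2 signal
#' units follows the hum stress-test scenario. This is [add_sine_noise()]
#' with hum-scale defaults.
#'
#' @inheritParams add_sine_noise
#' @export
add_hum <- function(rec, amplitude = 0.2, period_ms = 20) {
  add_sine_noise(rec, amplitude = amplitude, period_ms = period_ms)
}

#' Add window-correlated Gaussian noise to a recording
#'
#' Draws one independent Gaussian deviate `n_j ~ N(0, gauss_sd)` per sample
#' and adds to each sample the sum of the deviates in a centered window of
#' `sum_window` samples (default 11): `y_i += sum_{j=i-h}^{i+h} n_j`,
#' `h = (sum_window - 1)/2`. The resulting noise term is correlated over
#' `sum_window` consecutive points (lag-k autocorrelation
#' `(sum_window - k)/sum_window`) with interior standard deviation
#' `sqrt(sum_window) * gauss_sd`, mimicking the drift of real amplifiers
#' better than white noise. At the sweep edges the sum is truncated to
#' existing indices.
#'
#' @param rec A [recording()].
#' @param gauss_sd Standard deviation of the independent per-sample draws
#'   (default `0.02/5`).
#' @param sum_window Odd window size (default 11).
#' @param seed Optional integer seed.
#' @return The recording with noise added.
#' @export
add_correlated_noise <- function(rec, gauss_sd = 0.02 / 5, sum_window = 11L,
                                 seed = NULL) {
  stopifnot(inherits(rec, "recording"), gauss_sd >= 0)
  sum_window <- as.integer(sum_window)
  if (sum_window < 1L || sum_window %% 2L == 0L) {
    stop("'sum_window' must be an odd positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  h <- (sum_window - 1L) %/% 2L
  rec$sweeps <- lapply(rec$sweeps, function(x) {
    n <- length(x)
    draws <- stats::rnorm(n, 0, gauss_sd)
    cs <- c(0, cumsum(draws))
    i <- seq_len(n)
    term <- cs[pmin(i + h, n) + 1L] - cs[pmax(i - h, 1L)]
    x + term
  })
  rec
}

#' Gaussian scale for the hum stress-test noise
#'
#' The hum benchmark specifies random fluctuations with typical excursion
#' +/- 0.1 signal units; with an 11-point correlated sum the per-draw sd
#' that puts 3 summed-noise standard deviations at 0.1 is
#' `0.1 / (3 * sqrt(11))`.
#'
#' @param excursion Target 3-sigma excursion of the summed noise.
#' @param sum_window Correlation window (default 11).
#' @return Per-draw Gaussian sd.
#' @export
hum_noise_sd <- function(excursion = 0.1, sum_window = 11L) {
  excursion / (3 * sqrt(sum_window))
}
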