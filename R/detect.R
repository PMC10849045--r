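# Template-free miniature-event detection.
#
# The detector scans a trace in overlapping windows, takes the global
# extremum of each window as a candidate peak, walks backward from the peak
# against a moving average to locate the event onset and baseline, measures
# amplitude / 10-90% rise / half-width, fits a single-exponential decay, and
# applies kinetic acceptance filters. Overlapping ("compound") events are
# resolved by searching for a valley between two close peaks and subtracting
# the fitted decay of the earlier event from the later one's baseline.

#' Detection parameters
#'
#' Every knob of the miniature-event detector. Filter bounds left `NULL` are
#' not applied; a measured value that is undefined (e.g. a decay fit that
#' failed) fails any set filter on that quantity.
#'
#' @param direction `"positive"` for events deflecting above baseline,
#'   `"negative"` for below (e.g. inward currents).
#' @param auto_diameter_ms Width of the scanning window for [scan_auto()];
#'   successive windows shift by half this diameter.
#' @param search_radius_ms Half-width of the search window for
#'   [find_event_manual()].
#' @param ma_window Number of preceding samples averaged by the backward
#'   onset scan.
#' @param baseline_mode `"moving_average"` (default) compares each point with
#'   the mean of the `ma_window` preceding points; `"fixed_left_window"` uses
#'   the mean of a detached window left of the peak, for baselines corrupted
#'   near the onset (e.g. by mains hum: place the window about one hum period
#'   before the peak).
#' @param fixed_offset_ms,fixed_window_ms Gap between the peak and the right
#'   edge of the detached baseline window, and the window's width.
#' @param decay_method `"lm_fit"` (nonlinear least-squares single exponential)
#'   or `"one_over_e"` (curve-agnostic: time from the peak to the first 1/e
#'   amplitude crossing).
#' @param decay_fit_max_ms Maximum span fitted after the peak; `NA` (default)
#'   uses 5x the 1/e estimate when available, else 50 ms.
#' @param compound_enabled Resolve overlapping events?
#' @param min_peak_separation_ms Peaks closer than this are compound
#'   candidates.
#' @param valley_percent Percentage of the earlier peak's amplitude that a
#'   between-peak point must come closer to baseline than, for the two peaks
#'   to be split into separate events.
#' @param min_amplitude,max_amplitude,min_rise_ms,max_rise_ms,
#'   min_halfwidth_ms,max_halfwidth_ms,min_tau_ms,max_tau_ms Optional
#'   acceptance bounds, checked in the fixed order amplitude, rise,
#'   half-width, tau; the first violated criterion rejects the event.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(direction = c("positive", "negative"),
                             auto_diameter_ms = 20,
                             search_radius_ms = 10,
                             ma_window = 100L,
                             baseline_mode = c("moving_average", "fixed_left_window"),
                             fixed_offset_ms = 17.5,
                             fixed_window_ms = 5,
                             decay_method = c("lm_fit", "one_over_e"),
                             decay_fit_max_ms = NA_real_,
                             compound_enabled = TRUE,
                             min_peak_separation_ms = 25,
                             valley_percent = 50,
                             min_amplitude = NULL, max_amplitude = NULL,
                             min_rise_ms = NULL, max_rise_ms = NULL,
                             min_halfwidth_ms = NULL, max_halfwidth_ms = NULL,
                             min_tau_ms = NULL, max_tau_ms = NULL) {
  direction <- match.arg(direction)
  baseline_mode <- match.arg(baseline_mode)
  decay_method <- match.arg(decay_method)
  stopifnot(auto_diameter_ms > 0, search_radius_ms > 0, ma_window >= 1,
            fixed_offset_ms >= 0, fixed_window_ms > 0,
            valley_percent > 0, valley_percent <= 100,
            min_peak_separation_ms > 0)
  chk <- function(lo, hi, what) {
    if (!is.null(lo) && !is.null(hi) && lo > hi) {
      stop("filter min > max for ", what)
    }
  }
  chk(min_amplitude, max_amplitude, "amplitude")
  chk(min_rise_ms, max_rise_ms, "rise")
  chk(min_halfwidth_ms, max_halfwidth_ms, "halfwidth")
  chk(min_tau_ms, max_tau_ms, "tau")
  structure(list(
    direction = direction, auto_diameter_ms = auto_diameter_ms,
    search_radius_ms = search_radius_ms, ma_window = as.integer(ma_window),
    baseline_mode = baseline_mode, fixed_offset_ms = fixed_offset_ms,
    fixed_window_ms = fixed_window_ms, decay_method = decay_method,
    decay_fit_max_ms = decay_fit_max_ms, compound_enabled = compound_enabled,
    min_peak_separation_ms = min_peak_separation_ms,
    valley_percent = valley_percent,
    filters = list(
      amplitude = c(min = min_amplitude %||% NA_real_, max = max_amplitude %||% NA_real_),
      rise = c(min = min_rise_ms %||% NA_real_, max = max_rise_ms %||% NA_real_),
      halfwidth = c(min = min_halfwidth_ms %||% NA_real_, max = max_halfwidth_ms %||% NA_real_),
      tau = c(min = min_tau_ms %||% NA_real_, max = max_tau_ms %||% NA_real_))
  ), class = "detection_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dir_sign <- function(params) if (params$direction == "positive") 1 else -1

#' Locate the onset and baseline of a candidate event
#'
#' Walks backward from the peak, comparing each point with the mean of the
#' `ma_window` preceding points. The first visited point (latest in time)
#' that is not strictly on the event side of that moving average is the last
#' pre-event point; the next sample is the onset, and the moving-average
#' value there is the baseline. In `fixed_left_window` mode the baseline is
#' instead the mean of a detached window left of the peak and the crossing
#' is computed against that constant.
#'
#' @param trace Numeric vector (one sweep).
#' @param peak_index 1-based index of the candidate peak.
#' @param params A [detection_params()].
#' @param dt_ms Sampling interval in ms.
#' @return A list with `onset_index`, `baseline_value`, and `warn` (`TRUE`
#'   when no crossing was found and the onset was clamped).
#' @export
find_onset <- function(trace, peak_index, params, dt_ms) {
  n <- length(trace)
  if (peak_index < 2L || peak_index > n) stop("peak at trace edge")
  s <- .dir_sign(params)
  if (params$baseline_mode == "fixed_left_window") {
    off <- round(params$fixed_offset_ms / dt_ms)
    wid <- max(1L, round(params$fixed_window_ms / dt_ms))
    lo <- peak_index - off - wid
    hi <- peak_index - off - 1L
    if (hi >= 1L) {
      idx <- max(1L, lo):hi
      baseline <- mean(trace[idx])
      i <- peak_index - 1L
      while (i >= 1L) {
        if (s * trace[i] <= s * baseline) {
          return(list(onset_index = i + 1L, baseline_value = baseline, warn = FALSE))
        }
        i <- i - 1L
      }
      return(list(onset_index = 1L, baseline_value = baseline, warn = TRUE))
    }
    # window entirely before the trace: fall back to the moving average
  }
  W <- min(params$ma_window, peak_index - 1L)
  warn_short <- W < params$ma_window
  # cumulative-sum differences (not a rolling update, whose floating-point
  # residue would make the average over an exactly-flat stretch nonzero)
  cs <- c(0, cumsum(trace[seq_len(peak_index - 1L)]))
  i <- peak_index - 1L
  while (i >= W + 1L) {
    m <- (cs[i] - cs[i - W]) / W           # mean of trace[(i-W)..(i-1)]
    if (s * trace[i] <= s * m) {
      return(list(onset_index = i + 1L, baseline_value = m, warn = warn_short))
    }
    i <- i - 1L
  }
  list(onset_index = W + 1L, baseline_value = mean(trace[1:W]), warn = TRUE)
}

# linear-interpolated time (ms, relative to index `from`) of the LAST
# upward crossing of `level` at or before index `to`, on y (event-side signal)
.last_cross_up <- function(y, level, dt_ms) {
  m <- length(y)
  below <- y[-m] <= level & y[-1] > level
  i <- which(below)
  if (length(i) == 0L) return(NA_real_)
  i <- i[length(i)]
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  (i - 1 + frac) * dt_ms
}

# first downward crossing of `level` (ms relative to y[1])
.first_cross_down <- function(y, level, dt_ms) {
  m <- length(y)
  if (m < 2L) return(NA_real_)
  hit <- y[-m] >= level & y[-1] < level
  i <- which(hit)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1]
  frac <- (y[i] - level) / (y[i] - y[i + 1])
  (i - 1 + frac) * dt_ms
}

#' Measure amplitude, 10-90% rise time and half-width of an event
#'
#' Amplitude is the (direction-signed) difference between the peak sample
#' and the baseline. Rise time is the time between the latest 10% and 90%
#' amplitude crossings before the peak; half-width is the time between the
#' 50% crossing on the rise and the first 50% crossing after the peak, all
#' linearly interpolated between samples. Measures are invariant to adding a
#' constant to both trace and baseline.
#'
#' @param trace Numeric vector (one sweep).
#' @param onset_index,peak_index Event bounds (1-based, onset < peak).
#' @param baseline Scalar baseline, or a numeric vector as long as `trace`
#'   (used for compound events riding on the decay of an earlier event).
#' @param dt_ms Sampling interval in ms.
#' @param direction `"positive"` or `"negative"`.
#' @param stop_index Last index searched for the falling 50% crossing
#'   (default: end of trace).
#' @return A list with `amplitude` (signed along the detection direction; a
#'   non-positive value marks a candidate that does not deflect in the
#'   detection direction), `rise_10_90_ms`, `halfwidth_ms` (either may be
#'   `NA` when a crossing does not exist).
#' @export
measure_event <- function(trace, onset_index, peak_index, baseline, dt_ms,
                          direction = "positive", stop_index = length(trace)) {
  if (onset_index >= peak_index) stop("onset must precede the peak")
  s <- if (direction == "positive") 1 else -1
  bl_at <- function(rng) if (length(baseline) == 1L) baseline else baseline[rng]
  rng_up <- max(1L, onset_index - 1L):peak_index
  y_up <- s * (trace[rng_up] - bl_at(rng_up))
  amp <- y_up[length(y_up)]
  if (!is.finite(amp) || amp <= 0) {
    return(list(amplitude = amp, rise_10_90_ms = NA_real_, halfwidth_ms = NA_real_))
  }
  t10 <- .last_cross_up(y_up, 0.1 * amp, dt_ms)
  t90 <- .last_cross_up(y_up, 0.9 * amp, dt_ms)
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
  t50r <- .last_cross_up(y_up, 0.5 * amp, dt_ms)
  rng_dn <- peak_index:max(peak_index, stop_index)
  y_dn <- s * (trace[rng_dn] - bl_at(rng_dn))
  t50f <- .first_cross_down(y_dn, 0.5 * amp, dt_ms)
  hw <- if (is.na(t50r) || is.na(t50f)) NA_real_ else {
    (peak_index - rng_up[1]) * dt_ms - t50r + t50f
  }
  list(amplitude = amp, rise_10_90_ms = rise, halfwidth_ms = hw)
}

#' Fit the decay of an event with a single exponential
#'
#' In `lm_fit` mode, `B * exp(-t/tau)` is fitted by nonlinear least squares
#' (Gauss-Newton/port, the R counterpart of Levenberg-Marquardt curve
#' fitting) to the baseline-subtracted trace for `t >= 0` measured from the
#' peak, with starting values `B = amplitude` and `tau` = the 1/e crossing
#' time. In `one_over_e` mode tau is simply the interpolated time from the
#' peak to the earliest point at which the amplitude has decayed to 1/e of
#' the peak; for a true single-exponential decay the two modes agree. The
#' baseline is not a free parameter of the fit.
#'
#' @inheritParams measure_event
#' @param params A [detection_params()] (uses `decay_method` and
#'   `decay_fit_max_ms`).
#' @param stop_index Last sample available to the fit (next event onset or
#'   sweep end).
#' @return A list with `tau_ms` and `fit_amplitude` (`NA` on failure or when
#'   fewer than 5 samples are available).
#' @export
fit_decay <- function(trace, peak_index, baseline, params, dt_ms,
                      stop_index = length(trace)) {
  s <- .dir_sign(params)
  rng <- peak_index:max(peak_index, min(stop_index, length(trace)))
  bl <- if (length(baseline) == 1L) baseline else baseline[rng]
  y <- s * (trace[rng] - bl)
  amp <- y[1]
  if (!is.finite(amp) || amp <= 0 || length(y) < 5L) {
    return(list(tau_ms = NA_real_, fit_amplitude = NA_real_))
  }
  tau_e <- .first_cross_down(y, amp / exp(1), dt_ms)
  if (params$decay_method == "one_over_e") {
    return(list(tau_ms = tau_e, fit_amplitude = amp))
  }
  max_ms <- params$decay_fit_max_ms
  if (is.na(max_ms)) max_ms <- if (is.finite(tau_e %||% NA)) 5 * tau_e else 50
  if (is.na(max_ms) || !is.finite(max_ms)) max_ms <- 50
  m <- min(length(y), 1L + round(max_ms / dt_ms))
  if (m < 5L) return(list(tau_ms = NA_real_, fit_amplitude = NA_real_))
  yy <- y[seq_len(m)]
  tt <- (seq_len(m) - 1) * dt_ms
  tau0 <- if (is.na(tau_e) || tau_e <= 0) max_ms / 5 else tau_e
  fit <- tryCatch(
    stats::nls(yy ~ B * exp(-tt / tau),
               start = list(B = amp, tau = tau0),
               algorithm = "port",
               lower = c(B = 1e-12, tau = dt_ms / 10),
               control = stats::nls.control(maxiter = 100, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau_ms = NA_real_, fit_amplitude = NA_real_))
  cf <- stats::coef(fit)
  list(tau_ms = unname(cf["tau"]), fit_amplitude = unname(cf["B"]))
}

#' Decide whether a later peak is a separate (compound) event
#'
#' Two peaks closer than the minimum separation are split into two events
#' only if some point between them comes closer to the earlier event's
#' baseline than `valley_percent` of the earlier amplitude. When split, the
#' later event's onset is the between-peak point of minimum amplitude, and
#' its baseline at each sample is the earlier baseline plus the earlier
#' event's fitted decay extrapolated to that sample, so the later amplitude
#' is measured from the point to which the earlier event has decayed rather
#' than from the original baseline.
#'
#' @param earlier A measured event (row of [scan_auto()] output or
#'   equivalent list with `peak_index`, `baseline`, `amplitude`, `tau_ms`,
#'   `decay_fit_amplitude`).
#' @param later_peak_index Candidate peak index of the later event.
#' @param trace Numeric vector (one sweep).
#' @param params A [detection_params()].
#' @param dt_ms Sampling interval in ms.
#' @return A list with `is_separate`; when `TRUE`, also
#'   `later_onset_index` and `baseline_fun(idx)` evaluating the later
#'   event's baseline at arbitrary sample indices.
#' @export
resolve_compound <- function(earlier, later_peak_index, trace, params, dt_ms) {
  s <- .dir_sign(params)
  p1 <- earlier$peak_index
  if (later_peak_index - p1 < 2L) return(list(is_separate = FALSE))
  between <- (p1 + 1L):(later_peak_index - 1L)
  d <- s * (trace[between] - earlier$baseline)
  if (!any(d < (params$valley_percent / 100) * earlier$amplitude)) {
    return(list(is_separate = FALSE))
  }
  tau <- earlier$tau_ms
  B <- earlier$decay_fit_amplitude
  if (is.na(tau) || is.na(B)) {
    fb <- fit_decay(trace, p1, earlier$baseline,
                    within_params(params, decay_method = "one_over_e"),
                    dt_ms, stop_index = later_peak_index)
    tau <- fb$tau_ms
    B <- fb$fit_amplitude
    if (is.na(tau) || is.na(B)) return(list(is_separate = FALSE))
  }
  onset <- between[which.min(d)]
  base0 <- earlier$baseline
  baseline_fun <- function(idx) {
    base0 + s * B * exp(-((idx - p1) * dt_ms) / tau)
  }
  list(is_separate = TRUE, later_onset_index = onset, baseline_fun = baseline_fun)
}

#' Modify a copy of a detection_params object
#'
#' @param params A [detection_params()].
#' @param ... Named fields to replace.
#' @return The modified `detection_params`.
#' @export
within_params <- function(params, ...) {
  repl <- list(...)
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  params
}

#' Apply the kinetic acceptance filters to a measured event
#'
#' Checks run in the fixed order amplitude, rise, half-width, tau; the first
#' violated criterion sets `status = "rejected"` and `reject_reason` to that
#' criterion's name. An undefined (NA) measurement fails any set filter on
#' it, and a candidate that does not deflect in the detection direction
#' (non-positive amplitude) is always rejected as `"amplitude"`.
#'
#' @param event A one-row data.frame as produced by the measurement path.
#' @param params A [detection_params()].
#' @return `event` with `status` and `reject_reason` set.
#' @export
apply_filters <- function(event, params) {
  fl <- params$filters
  fails <- function(value, bounds) {
    (!is.na(bounds["min"]) && (is.na(value) || value < bounds["min"])) ||
    (!is.na(bounds["max"]) && (is.na(value) || value > bounds["max"]))
  }
  reason <- ""
  if (is.na(event$amplitude) || event$amplitude <= 0 ||
      fails(event$amplitude, fl$amplitude)) {
    reason <- "amplitude"
  } else if (fails(event$rise_10_90_ms, fl$rise)) {
    reason <- "rise"
  } else if (fails(event$halfwidth_ms, fl$halfwidth)) {
    reason <- "halfwidth"
  } else if (fails(event$tau_ms, fl$tau)) {
    reason <- "tau"
  }
  event$status <- if (nzchar(reason)) "rejected" else "accepted"
  event$reject_reason <- reason
  event
}

.empty_events <- function() {
  data.frame(sweep = integer(0), onset_index = integer(0),
             peak_index = integer(0), onset_time_s = numeric(0),
             peak_time_s = numeric(0), baseline = numeric(0),
             amplitude = numeric(0), rise_10_90_ms = numeric(0),
             halfwidth_ms = numeric(0), tau_ms = numeric(0),
             decay_fit_amplitude = numeric(0), compound = logical(0),
             status = character(0), reject_reason = character(0))
}

# quick amplitude screen for a candidate peak: onset scan + baseline only.
# The filter chain rejects on amplitude before any kinetics are computed
# ("as soon as one criterion is violated ... proceeds to the next peak"),
# so candidates failing the amplitude bounds never count as detected events
# and must not truncate a neighbour's decay-fit span.
.screen_candidate <- function(trace, p, params, dt_ms) {
  s <- .dir_sign(params)
  on <- tryCatch(find_onset(trace, p, params, dt_ms), error = function(e) NULL)
  if (is.null(on) || on$onset_index >= p) return(NULL)
  amp <- s * (trace[p] - on$baseline_value)
  fl <- params$filters$amplitude
  pass <- is.finite(amp) && amp > 0 &&
    !(!is.na(fl["min"]) && amp < fl["min"]) &&
    !(!is.na(fl["max"]) && amp > fl["max"])
  list(peak_index = p, onset_index = on$onset_index,
       baseline = on$baseline_value, amplitude = amp, pass = pass)
}

.event_row <- function(sweep, onset, p, t0, dt_s, baseline, amplitude,
                       rise = NA_real_, hw = NA_real_, tau = NA_real_,
                       fit_amp = NA_real_, compound = FALSE) {
  data.frame(
    sweep = sweep, onset_index = onset, peak_index = p,
    onset_time_s = t0 + (onset - 1) * dt_s,
    peak_time_s = t0 + (p - 1) * dt_s,
    baseline = baseline, amplitude = amplitude,
    rise_10_90_ms = rise, halfwidth_ms = hw, tau_ms = tau,
    decay_fit_amplitude = fit_amp, compound = compound,
    status = "", reject_reason = "")
}

# full measurement of a screened candidate; prev_event is the previously
# accepted event (compound anchor), next_onset the next screened survivor's
# onset index (decay-span limit) or NA.
.measure_candidate <- function(trace, p, params, dt_ms, t0, dt_s, sweep,
                               prev_event = NULL, next_onset = NA_integer_,
                               screened_onset = NULL, screened_baseline = NULL) {
  s <- .dir_sign(params)
  n <- length(trace)
  compound <- FALSE
  baseline_vec <- NULL

  if (!is.null(prev_event) && isTRUE(params$compound_enabled) &&
      (p - prev_event$peak_index) * dt_ms < params$min_peak_separation_ms) {
    rc <- resolve_compound(prev_event, p, trace, params, dt_ms)
    if (!rc$is_separate) return(NULL)       # part of the earlier event's decay
    compound <- TRUE
    onset <- rc$later_onset_index
    baseline_vec <- numeric(n)
    # decay extrapolation is only meaningful from the earlier peak on
    rng <- prev_event$peak_index:n
    baseline_vec[rng] <- rc$baseline_fun(rng)
    if (prev_event$peak_index > 1L) {
      baseline_vec[seq_len(prev_event$peak_index - 1L)] <-
        rc$baseline_fun(prev_event$peak_index)
    }
    baseline_at_peak <- baseline_vec[p]
  } else if (!is.null(screened_onset)) {
    onset <- screened_onset
    baseline_at_peak <- screened_baseline
  } else {
    on <- find_onset(trace, p, params, dt_ms)
    onset <- on$onset_index
    baseline_at_peak <- on$baseline_value
  }
  if (onset >= p) return(NULL)              # degenerate candidate

  # span searched for the falling half-width crossing and the decay fit:
  # up to the next detected event's onset (valley rule applies there for
  # compound pairs via that event's own onset) or the sweep end
  stop_idx <- if (is.na(next_onset)) n else max(p, next_onset - 1L)

  bl <- if (compound) baseline_vec else baseline_at_peak
  meas <- measure_event(trace, onset, p, bl, dt_ms,
                        direction = params$direction, stop_index = stop_idx)
  dec <- fit_decay(trace, p, bl, params, dt_ms, stop_index = stop_idx)
  ev <- .event_row(sweep, onset, p, t0, dt_s, baseline_at_peak,
                   meas$amplitude, meas$rise_10_90_ms, meas$halfwidth_ms,
                   dec$tau_ms, dec$fit_amplitude, compound)
  apply_filters(ev, params)
}

#' Automatically detect all miniature events in a recording
#'
#' Each sweep is scanned in a series of windows of width `auto_diameter_ms`,
#' shifted by half the diameter per iteration. The global extremum of each
#' window (maximum for positive-going events) is a candidate peak;
#' candidates sitting on a window's first or last sample are deferred to the
#' window where they are interior, and duplicate peaks from overlapping
#' windows are processed once. Each unique candidate is measured
#' ([find_onset()], [measure_event()], [fit_decay()]), compound-resolved
#' against the previous accepted event, and filtered. Rejected events are
#' retained in the output with their rejection reason.
#'
#' @param rec A [recording()].
#' @param params A [detection_params()].
#' @return A data.frame of events sorted by peak time, with columns `sweep`,
#'   `onset_index`, `peak_index`, `onset_time_s`, `peak_time_s`, `baseline`,
#'   `amplitude`, `rise_10_90_ms`, `halfwidth_ms`, `tau_ms`,
#'   `decay_fit_amplitude`, `compound`, `status`, `reject_reason`.
#' @export
scan_auto <- function(rec, params = detection_params()) {
  stopifnot(inherits(rec, "recording"), inherits(params, "detection_params"))
  dt_s <- rec$dt
  dt_ms <- dt_s * 1e3
  s <- .dir_sign(params)
  out <- list()
  for (sw in seq_len(n_sweeps(rec))) {
    trace <- rec$sweeps[[sw]]
    n <- length(trace)
    D <- max(2L, round(params$auto_diameter_ms / dt_ms))
    hop <- max(1L, D %/% 2L)
    starts <- if (n <= D) 1L else seq(1L, n - hop, by = hop)
    cand <- integer(0)
    for (a in starts) {
      b <- min(a + D - 1L, n)
      if (b - a < 1L) next
      w <- s * trace[a:b]
      p <- a + which.max(w) - 1L
      if (p == a || p == b) next            # deferred to the window where interior
      cand <- c(cand, p)
    }
    cand <- sort(unique(cand))
    # stage 1: amplitude screen; candidates failing it are rejected
    # immediately ("amplitude") and never anchor a neighbour's measurement
    screens <- lapply(cand, .screen_candidate, trace = trace,
                      params = params, dt_ms = dt_ms)
    keep <- !vapply(screens, is.null, logical(1))
    cand <- cand[keep]; screens <- screens[keep]
    pass <- vapply(screens, `[[`, logical(1), "pass")
    for (k in which(!pass)) {
      ev <- .event_row(sw, screens[[k]]$onset_index, cand[k], rec$t0, dt_s,
                       screens[[k]]$baseline, screens[[k]]$amplitude)
      ev$status <- "rejected"; ev$reject_reason <- "amplitude"
      out[[length(out) + 1L]] <- ev
    }
    # stage 2: full measurement of the survivors, in time order
    surv <- which(pass)
    prev <- NULL
    for (k in seq_along(surv)) {
      i <- surv[k]
      nxt_on <- if (k < length(surv)) screens[[surv[k + 1L]]]$onset_index else NA_integer_
      ev <- .measure_candidate(trace, cand[i], params, dt_ms, rec$t0, dt_s,
                               sweep = sw, prev_event = prev,
                               next_onset = nxt_on,
                               screened_onset = screens[[i]]$onset_index,
                               screened_baseline = screens[[i]]$baseline)
      if (is.null(ev)) next
      out[[length(out) + 1L]] <- ev
      if (identical(ev$status, "accepted")) prev <- ev
    }
  }
  if (length(out) == 0L) return(.empty_events())
  res <- do.call(rbind, out)
  res <- res[order(res$sweep, res$peak_time_s), ]
  rownames(res) <- NULL
  res
}

#' Detect a single event around a given time
#'
#' Searches for the global extremum within `search_radius_ms` of
#' `center_time_s` and runs the same measurement path as [scan_auto()]. This
#' is the headless counterpart of clicking near an event in an interactive
#' viewer; the returned row carries the accept/reject status and reason.
#'
#' @param rec A [recording()].
#' @param center_time_s Center of the search window in seconds.
#' @param params A [detection_params()].
#' @param sweep Sweep index (default 1).
#' @return A one-row event data.frame (see [scan_auto()]), or `NULL` when
#'   the window contains no samples.
#' @export
find_event_manual <- function(rec, center_time_s, params = detection_params(),
                              sweep = 1L) {
  stopifnot(inherits(rec, "recording"))
  dt_s <- rec$dt
  dt_ms <- dt_s * 1e3
  r_s <- params$search_radius_ms * 1e-3
  sl <- slice_recording(rec, center_time_s - r_s, center_time_s + r_s, sweep)
  if (length(sl$samples) == 0L) return(NULL)
  s <- .dir_sign(params)
  p <- sl$first_index + which.max(s * sl$samples) - 1L
  trace <- rec$sweeps[[sweep]]
  if (p < 2L || p >= length(trace)) return(NULL)
  ev <- .measure_candidate(trace, p, params, dt_ms, rec$t0, dt_s, sweep = sweep)
  if (is.null(ev)) {
    # degenerate candidate (e.g. flat window): report it as a rejected
    # zero-amplitude event rather than silently returning nothing
    ev <- apply_filters(.event_row(sweep, max(1L, p - 1L), p, rec$t0, dt_s,
                                   baseline = trace[p], amplitude = 0), params)
  }
  ev
}
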