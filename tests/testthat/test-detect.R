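dp <- function(...) detection_params(...)

test_that("backward moving-average scan finds the onset and baseline", {
  # hand-traced 6-sample examples (1-based indices)
  r1 <- find_onset(c(0, 0, 0, 0, 0.5, 2), 6, dp(ma_window = 3), dt_ms = 1)
  expect_equal(r1$onset_index, 5L)
  expect_equal(r1$baseline_value, 0)
  r2 <- find_onset(c(0, 0, 0, 0, 1, 2), 6, dp(ma_window = 3), dt_ms = 1)
  expect_equal(r2$onset_index, 5L)
  expect_equal(r2$baseline_value, 0)
  expect_error(find_onset(c(0, 1), 1, dp(), 1), "edge")
})

test_that("onset and baseline track a drifting baseline", {
  # linear drift of 2% of amplitude per ms under a sharp event, with ripple.
  # On a noiseless monotone drift the trace sits above the moving average
  # everywhere and the crossing cannot occur; ripple restores crossings and
  # the onset lands within ~1 ms of the true start, with the baseline at
  # the local drift level rather than zero.
  dt_ms <- 0.1
  wf <- sharp_waveform(2, 1, 10, dt_ms)
  n_lead <- 500L
  n <- n_lead + length(wf$samples)
  t_ms <- (seq_len(n) - 1) * dt_ms
  trace <- c(numeric(n_lead), wf$samples) + 0.02 * t_ms +
    0.05 * sin(2 * pi * t_ms)
  peak <- n_lead + round(2 / dt_ms) + 1L
  r <- find_onset(trace, peak, dp(ma_window = 20), dt_ms)
  expect_lte(abs(r$onset_index - (n_lead + 1L)), 10L)
  expect_equal(r$baseline_value, 0.02 * n_lead * dt_ms, tolerance = 0.12)
})

test_that("fixed_left_window mode measures against a detached baseline", {
  dt_ms <- 0.1
  trace <- c(rep(2, 300), rep(2, 100), 2 + sharp_waveform(1, 1, 8, dt_ms)$samples)
  peak <- 400L + round(1 / dt_ms) + 1L
  p <- dp(baseline_mode = "fixed_left_window", fixed_offset_ms = 10,
          fixed_window_ms = 5)
  r <- find_onset(trace, peak, p, dt_ms)
  expect_equal(r$baseline_value, 2)
  expect_lt(abs(r$onset_index - 401L), 3)
})

test_that("measurement recovers analytic amplitude, rise and half-width", {
  fix <- clean_sharp_recording()
  tr <- fix$recording$sweeps[[1]]
  m <- measure_event(tr, fix$onset_index, fix$peak_index, 0, 0.1)
  expect_equal(m$amplitude, 1, tolerance = 1e-9)
  expect_equal(m$rise_10_90_ms, 1.6, tolerance = 0.1)      # within dt
  # near-instant rise: half-width ~ tau * ln 2
  wf <- sharp_waveform(0.01, 1, 10, 0.1)
  tr2 <- c(numeric(50), wf$samples)
  m2 <- measure_event(tr2, 50L, 52L, 0, 0.1)
  expect_equal(m2$halfwidth_ms, 10 * log(2), tolerance = 0.15)
  # translation invariance
  m3 <- measure_event(tr + 7.5, fix$onset_index, fix$peak_index, 7.5, 0.1)
  expect_equal(m3[c("amplitude", "rise_10_90_ms", "halfwidth_ms")],
               m[c("amplitude", "rise_10_90_ms", "halfwidth_ms")],
               tolerance = 1e-9)
})

test_that("decay fitting matches the exact model in both modes", {
  fix <- clean_sharp_recording(tau = 10)
  tr <- fix$recording$sweeps[[1]]
  lm <- fit_decay(tr, fix$peak_index, 0, dp(decay_method = "lm_fit"), 0.1)
  oe <- fit_decay(tr, fix$peak_index, 0, dp(decay_method = "one_over_e"), 0.1)
  expect_equal(lm$tau_ms, 10, tolerance = 1e-3)
  expect_equal(oe$tau_ms, 10, tolerance = 1e-3)
  # the curve-agnostic mode equals the fit on true single exponentials
  expect_lt(abs(oe$tau_ms - lm$tau_ms) / lm$tau_ms, 0.01)
})

test_that("lm_fit equals a brute-force grid-search least-squares oracle", {
  # 50 noisy single-exponential decays; both routes see identical data
  set.seed(303)
  dt_ms <- 0.1
  worst <- 0
  for (k in 1:50) {
    tau <- runif(1, 3, 25)
    A <- runif(1, 0.5, 2.5)
    n <- 401L
    y <- A * exp(-(0:(n - 1)) * dt_ms / tau) + rnorm(n, 0, 0.013)
    trace <- c(numeric(10), y)
    fit <- fit_decay(trace, 11L, 0, dp(decay_fit_max_ms = 40), dt_ms,
                     stop_index = 11L + n - 1L)
    oracle <- grid_search_tau(y[1:(1L + round(40 / dt_ms))], dt_ms)
    worst <- max(worst, abs(fit$tau_ms - oracle) / oracle)
  }
  expect_lt(worst, 0.01)
})

test_that("biexp decay fit matches the grid-search oracle despite model mismatch", {
  wf <- biexp_waveform(5, 10, 1.5, 0.1)
  peak <- which.max(wf$samples)
  trace <- c(numeric(20), wf$samples)
  fit <- fit_decay(trace, 20L + peak, 0, dp(decay_fit_max_ms = 40), 0.1,
                   stop_index = length(trace))
  y <- wf$samples[peak:min(length(wf$samples), peak + 400L)]
  oracle <- grid_search_tau(y, 0.1)
  expect_lt(abs(fit$tau_ms - oracle) / oracle, 0.01)
  expect_gt(abs(fit$tau_ms - 10), 0.05)   # differs from tau2 alone
})

test_that("compound events split at a valley and subtract the earlier decay", {
  dt_ms <- 0.1
  w1 <- sharp_waveform(1, 1, 10, dt_ms)
  n <- 2000L
  tr <- numeric(n)
  o1 <- 301L; o2 <- o1 + 300L                  # peaks 30 ms apart
  tr[o1:(o1 + length(w1$samples) - 1L)] <- w1$samples
  idx2 <- o2:(o2 + length(w1$samples) - 1L)
  tr[idx2] <- tr[idx2] + w1$samples
  rec <- recording(tr, dt = dt_ms * 1e-3)
  p <- dp(min_amplitude = 0.3, min_peak_separation_ms = 40, valley_percent = 50)
  ev <- scan_auto(rec, p)
  acc <- ev[ev$status == "accepted", ]
  expect_equal(nrow(acc), 2L)
  expect_true(acc$compound[2])
  # later amplitude recovered after subtracting the exp(-30/10) ~ 0.05 residue
  expect_equal(acc$amplitude[2], 1, tolerance = 0.02)
  expect_equal(acc$amplitude[1], 1, tolerance = 0.01)

  # same pair 2 ms apart: no valley below 50%, single event
  tr2 <- numeric(n)
  tr2[o1:(o1 + length(w1$samples) - 1L)] <- w1$samples
  idx3 <- (o1 + 20L):(o1 + 20L + length(w1$samples) - 1L)
  tr2[idx3] <- tr2[idx3] + w1$samples
  ev2 <- scan_auto(recording(tr2, dt = dt_ms * 1e-3), p)
  expect_equal(sum(ev2$status == "accepted"), 1L)
})

test_that("a 20 Hz train is resolved with amplitudes from the decayed level", {
  dt_ms <- 0.1
  wf <- sharp_waveform(1, 1, 15, dt_ms)
  n <- 4000L
  tr <- numeric(n)
  onsets <- 501L + (0:4) * 500L               # 5 events, 50 ms apart
  for (o in onsets) {
    idx <- o:min(n, o + length(wf$samples) - 1L)
    tr[idx] <- tr[idx] + wf$samples[seq_along(idx)]
  }
  p <- dp(min_amplitude = 0.3, min_peak_separation_ms = 60, valley_percent = 50)
  ev <- scan_auto(recording(tr, dt = dt_ms * 1e-3), p)
  acc <- ev[ev$status == "accepted", ]
  expect_equal(nrow(acc), 5L)
  expect_true(all(acc$compound[-1]))
  # amplitude measured from the previous event's decay, not the original baseline
  expect_equal(acc$amplitude, rep(1, 5), tolerance = 0.05)
  # the raw trace peak of event 2 sits above 1 by the summed residue
  expect_gt(max(tr[onsets[2]:(onsets[2] + 20L)]), 1.02)
})

test_that("filters reject in fixed order with named reasons", {
  ev <- data.frame(amplitude = 0.3, rise_10_90_ms = 1, halfwidth_ms = 5,
                   tau_ms = NA_real_)
  r1 <- apply_filters(ev, dp(min_amplitude = 0.5))
  expect_equal(r1$status, "rejected")
  expect_equal(r1$reject_reason, "amplitude")
  r2 <- apply_filters(ev, dp())
  expect_equal(r2$status, "accepted")
  expect_equal(r2$reject_reason, "")
  r3 <- apply_filters(ev, dp(max_tau_ms = 50))      # tau undefined fails the filter
  expect_equal(r3$reject_reason, "tau")
  r4 <- apply_filters(transform(ev, rise_10_90_ms = 9), dp(max_rise_ms = 5))
  expect_equal(r4$reject_reason, "rise")
  expect_error(dp(min_amplitude = 2, max_amplitude = 1), "min > max")
})

test_that("auto scan recovers a clean event exactly and ignores flat traces", {
  fix <- clean_sharp_recording()
  p <- dp(min_amplitude = 0.3)
  ev <- scan_auto(fix$recording, p)
  acc <- ev[ev$status == "accepted", ]
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$amplitude, 1, tolerance = 1e-6)
  expect_equal(acc$tau_ms, 10, tolerance = 0.01)
  expect_equal(acc$peak_index, fix$peak_index)

  flat <- recording(numeric(3000), dt = 1e-4)
  expect_equal(sum(scan_auto(flat, p)$status == "accepted"), 0L)
})

test_that("detection is deterministic, sign-symmetric and translation-invariant", {
  sim <- build_recording(20, seed = 77)
  rec <- add_correlated_noise(sim$recording, seed = 78)
  p <- dp(min_amplitude = 0.3)
  ev1 <- scan_auto(rec, p)
  expect_identical(ev1, scan_auto(rec, p))
  # sign symmetry
  neg <- rec
  neg$sweeps <- lapply(neg$sweeps, function(x) -x)
  ev2 <- scan_auto(neg, within_params(p, direction = "negative"))
  expect_equal(ev2$amplitude, ev1$amplitude)
  expect_equal(ev2$baseline, -ev1$baseline)
  expect_equal(ev2$peak_index, ev1$peak_index)
  expect_equal(ev2$tau_ms, ev1$tau_ms)
  # translation invariance
  shifted <- rec
  shifted$sweeps <- lapply(shifted$sweeps, function(x) x + 3)
  ev3 <- scan_auto(shifted, p)
  expect_equal(ev3$baseline, ev1$baseline + 3)
  ev3$baseline <- ev1$baseline
  expect_equal(ev3, ev1)
})

test_that("noise-free generator output is recovered essentially exactly", {
  # biexp events, curve-agnostic decay mode (a single-exponential fit to a
  # biexp decay is model-mismatched; the 1/e time is the like-for-like truth)
  sim <- build_recording(100, seed = 99)
  p <- dp(min_amplitude = 0.3, decay_method = "one_over_e")
  ev <- scan_auto(sim$recording, p)
  acc <- ev[ev$status == "accepted", ]
  pairs <- match_events(sim$truth$peak_time_s, acc$peak_time_s, 2)
  expect_equal(nrow(pairs), 100L)
  amp_err <- abs(acc$amplitude[pairs$detected_idx] - sim$truth$amplitude)
  expect_lt(max(amp_err), 1e-3)
  onset_err <- abs(acc$onset_time_s[pairs$detected_idx] - sim$truth$onset_time_s)
  expect_lte(max(onset_err), sim$recording$dt + 1e-12)
  tau_rel <- abs(acc$tau_ms[pairs$detected_idx] - sim$truth$tau_1e_ms) /
    sim$truth$tau_1e_ms
  expect_lt(max(tau_rel), 0.01)

  # sharp events with lm_fit: tau is exact; the off-grid linear peak makes
  # amplitude good only to ~A*dt/(t_rise + tau)
  sim2 <- build_recording(50, event_sampler = sample_sharp_specs, seed = 100)
  ev2 <- scan_auto(sim2$recording, dp(min_amplitude = 0.3))
  acc2 <- ev2[ev2$status == "accepted", ]
  pairs2 <- match_events(sim2$truth$peak_time_s, acc2$peak_time_s, 2)
  expect_equal(nrow(pairs2), 50L)
  tau_rel2 <- abs(acc2$tau_ms[pairs2$detected_idx] - sim2$truth$tau_1e_ms) /
    sim2$truth$tau_1e_ms
  expect_lt(max(tau_rel2), 0.01)
  tol2 <- sim2$truth$amplitude * 0.1 / (sim2$truth$t_rise + sim2$truth$tau_decay)
  expect_true(all(abs(acc2$amplitude[pairs2$detected_idx] -
                        sim2$truth$amplitude) < pmax(tol2, 1e-3)))
})

test_that("manual search matches auto detection and honours the radius", {
  fix <- clean_sharp_recording()
  p <- dp(min_amplitude = 0.3)
  auto <- scan_auto(fix$recording, p)
  auto <- auto[auto$status == "accepted", ]
  man <- find_event_manual(fix$recording, auto$peak_time_s[1], p)
  expect_equal(man$peak_index, auto$peak_index[1])
  expect_equal(man$amplitude, auto$amplitude[1], tolerance = 1e-9)
  expect_equal(man$tau_ms, auto$tau_ms[1], tolerance = 1e-6)

  # centered in flat baseline: rejected with reason "amplitude"
  man2 <- find_event_manual(fix$recording, 0.005, within_params(p, search_radius_ms = 3))
  expect_equal(man2$status, "rejected")
  expect_equal(man2$reject_reason, "amplitude")

  # radius spanning two peaks: the larger extremum wins
  dt_ms <- 0.1
  small <- sharp_waveform(1, 0.6, 10, dt_ms)$samples
  big <- sharp_waveform(1, 1.4, 10, dt_ms)$samples
  tr <- numeric(1500)
  tr[301:(300 + length(small))] <- small
  tr[801:(800 + length(big))] <- tr[801:(800 + length(big))] + big
  man3 <- find_event_manual(recording(tr, 1e-4), 0.055,
                            within_params(p, search_radius_ms = 40))
  expect_equal(man3$peak_index, 800L + which.max(big))
})
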