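test_that("biexp peak time matches the closed form and a dense-grid oracle", {
  # closed form t* = tau1 * log(1 + tau2/tau1)
  expect_equal(biexp_peak_time(5, 10), 5 * log(3), tolerance = 1e-12)
  expect_equal(biexp_peak_time(5, 5), 5 * log(2), tolerance = 1e-12)
  # oracle: argmax on a fine grid
  tg <- seq(0, 60, by = 1e-4)
  yg <- (1 - exp(-tg / 5)) * exp(-tg / 10)
  expect_equal(biexp_peak_time(5, 10), tg[which.max(yg)], tolerance = 1e-3)
})

test_that("biexp waveform peaks at the requested amplitude", {
  for (spec in list(c(5, 10, 1.5), c(2.2, 14.9, 0.5), c(9.7, 2.1, 2.5))) {
    wf <- biexp_waveform(spec[1], spec[2], spec[3], dt_ms = 0.1)
    expect_lt(abs(max(wf$samples) - spec[3]), spec[3] * 1e-3)
    expect_equal(length(wf$samples), ceiling(5 * (spec[1] + spec[2]) / 0.1))
    # decayed below 1% of amplitude at the end of the segment
    expect_lt(wf$samples[length(wf$samples)], 0.01 * spec[3])
  }
})

test_that("sharp waveform has exact analytic kinetics", {
  wf <- sharp_waveform(t_rise = 2, amplitude = 1, tau_decay = 10, dt_ms = 0.1)
  expect_equal(wf$rise_10_90_ms, 1.6)
  expect_equal(wf$tau_1e_ms, 10)
  expect_equal(wf$samples[round(2 / 0.1) + 1], 1)  # value A at t = t_rise
})

test_that("true_kinetics recovers known kinetics by bisection", {
  # pure exponential decay appended to an instant rise
  f_exp <- function(t) ifelse(t <= 0.001, t / 0.001, exp(-(t - 0.001) / 7))
  k <- true_kinetics(f_exp, peak_time = 0.001, amplitude = 1)
  expect_equal(k$tau_1e_ms, 7, tolerance = 1e-6)
  # linear rise over 5 ms
  f_lin <- function(t) ifelse(t <= 5, t / 5, exp(-(t - 5) / 3))
  expect_equal(true_kinetics(f_lin, 5, 1)$rise_10_90_ms, 4, tolerance = 1e-6)
  # biexp vs dense-grid brute force at dt = 1e-4 ms
  f_bi <- function(t) (1 - exp(-t / 5)) * exp(-t / 10) / 0.3849002
  tp <- biexp_peak_time(5, 10)
  amp <- f_bi(tp)
  k2 <- true_kinetics(f_bi, tp, amp)
  tg <- seq(0, 200, by = 1e-4)
  yg <- f_bi(tg)
  t10 <- tg[which(yg[-length(yg)] <= 0.1 * amp & yg[-1] > 0.1 * amp)[1]]
  t90 <- tg[which(yg[-length(yg)] <= 0.9 * amp & yg[-1] > 0.9 * amp)[1]]
  dec <- which(tg > tp & yg <= amp / exp(1))[1]
  expect_equal(k2$rise_10_90_ms, t90 - t10, tolerance = 1e-3)
  expect_equal(k2$tau_1e_ms, tg[dec] - tp, tolerance = 1e-3)
})

test_that("build_recording places events per the spacer rule, deterministically", {
  sim <- build_recording(1, spacing_range = c(100L, 100L), dt_ms = 0.1, seed = 5)
  expect_equal(sim$truth$onset_time_s, 100 * 0.1 * 1e-3)
  expect_error(build_recording(0), ">= 1")

  sim2 <- build_recording(25, seed = 11)
  expect_true(all(diff(sim2$truth$onset_time_s) > 0))
  expect_true(all(sim2$truth$peak_time_s > sim2$truth$onset_time_s))
  # bit-identical replay under the same seed
  sim3 <- build_recording(25, seed = 11)
  expect_identical(sim2$recording$sweeps, sim3$recording$sweeps)
  expect_identical(sim2$truth, sim3$truth)
})

test_that("noise-free events decay below 1% of amplitude before the next onset", {
  sim <- build_recording(30, seed = 21)
  tr <- sim$recording$sweeps[[1]]
  dt <- sim$recording$dt
  for (k in seq_len(nrow(sim$truth) - 1)) {
    pre_onset <- round(sim$truth$onset_time_s[k + 1] / dt)  # sample before next event
    expect_lt(abs(tr[pre_onset]), 0.01 * sim$truth$amplitude[k])
  }
})

test_that("sine noise adds the stated sinusoid", {
  rec <- recording(numeric(1000), dt = 1e-4)   # 0.1 ms sampling
  same <- add_sine_noise(rec, amplitude = 0)
  expect_identical(same$sweeps, rec$sweeps)
  noisy <- add_sine_noise(rec, amplitude = 0.02, period_ms = 1)
  t_ms <- rec_times(noisy) * 1e3
  expect_equal(noisy$sweeps[[1]], 0.02 * sin(2 * pi * t_ms / 1), tolerance = 1e-12)
  # quarter-period sample hits the full amplitude: sin(pi/2) = 1
  fine <- add_sine_noise(recording(numeric(40), dt = 2.5e-5), 0.02, 1)
  expect_equal(fine$sweeps[[1]][11], 0.02)   # t = 0.25 ms
  # zero mean over integer periods
  expect_lt(abs(mean(noisy$sweeps[[1]])), 1e-12)
})

test_that("correlated noise has the summed-window variance and autocorrelation", {
  n <- 1e6
  rec <- recording(numeric(n), dt = 1e-4)
  expect_identical(add_correlated_noise(rec, gauss_sd = 0)$sweeps, rec$sweeps)
  sd0 <- 0.02 / 5
  noisy <- add_correlated_noise(rec, gauss_sd = sd0, sum_window = 11L, seed = 9)
  x <- noisy$sweeps[[1]][6:(n - 5)]           # interior samples only
  expect_equal(sd(x), sqrt(11) * sd0, tolerance = 0.02)
  # lag-1 autocorrelation of the overlapping-window sum is 10/11
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 10 / 11), 0.02)
  expect_error(add_correlated_noise(rec, sum_window = 10L), "odd")
})

test_that("hum has the stated period and peak-to-peak range", {
  n <- 4000                                    # 400 ms at 10 kHz
  rec <- recording(numeric(n), dt = 1e-4)
  hum <- add_hum(rec, amplitude = 0.2, period_ms = 20)
  x <- hum$sweeps[[1]]
  expect_equal(max(x) - min(x), 0.4, tolerance = 1e-6)
  # 50 Hz: peaks 20 ms apart
  expect_identical(add_hum(rec, amplitude = 0)$sweeps, rec$sweeps)
  crossings <- which(x[-n] < 0 & x[-1] >= 0)
  # 20 ms = 200 samples between upward zero crossings (+/- 1 for float
  # jitter of sin at exact period multiples)
  expect_true(all(abs(diff(crossings) - 200L) <= 1L))
  expect_equal(mean(diff(crossings)), 200, tolerance = 1e-3)
})
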