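# Shared fixtures: small deterministic traces and parameter sets used across
# test files. Everything is generated in code; nothing is stored on disk.

# a single clean sharp event (A = 1, t_rise = 2 ms, tau = 10 ms) on a flat
# zero baseline, 10 kHz, with 20 ms of leading baseline
clean_sharp_recording <- function(lead_samples = 200L, t_rise = 2,
                                  amplitude = 1, tau = 10, dt_ms = 0.1) {
  wf <- sharp_waveform(t_rise, amplitude, tau, dt_ms)
  trace <- c(numeric(lead_samples), wf$samples, numeric(200L))
  list(recording = recording(trace, dt = dt_ms * 1e-3),
       onset_index = lead_samples + 1L,
       peak_index = lead_samples + round(t_rise / dt_ms) + 1L,
       waveform = wf)
}

# brute-force grid-search least-squares single-exponential fit: profiles the
# amplitude analytically for each tau on a fine multiplicative grid, then
# refines the best tau by golden-section search. Independent of fit_decay.
grid_search_tau <- function(y, dt_ms, tau_lo = 0.5, tau_hi = 50) {
  tt <- (seq_along(y) - 1) * dt_ms
  sse <- function(tau) {
    e <- exp(-tt / tau)
    b <- sum(y * e) / sum(e * e)
    sum((y - b * e)^2)
  }
  taus <- exp(seq(log(tau_lo), log(tau_hi), length.out = 2000))
  best <- taus[which.min(vapply(taus, sse, numeric(1)))]
  stats::optimize(sse, lower = best * 0.99, upper = best * 1.01,
                  tol = 1e-10)$minimum
}
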