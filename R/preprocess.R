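# Trace preprocessing: boxcar and zero-phase Bessel low-pass filtering,
# baseline subtraction, and (unaligned) sweep averaging.
#
# The Bessel design is done from first principles because no DSP package is
# assumed: the analog prototype poles are the roots of the reverse Bessel
# polynomial, the prototype is magnitude-normalized so its -3 dB point sits
# at the requested cutoff, and the digital filter is obtained by bilinear
# transform with frequency prewarping. The filter is applied
# forward-backward (zero phase) so that event onsets and rise times are not
# delayed; the magnitude response is squared by the two passes.

#' Boxcar (centered moving-average) filter
#'
#' Each sample is replaced by the mean of a centered window of `width`
#' samples. Edges use reflected padding so the output length equals the
#' input length and baselines do not droop at the trace ends. DC (a constant
#' trace) is preserved exactly.
#'
#' @param rec A [recording()].
#' @param width Odd window width in samples, at most the sweep length.
#' @return The filtered recording.
#' @export
boxcar_filter <- function(rec, width) {
  stopifnot(inherits(rec, "recording"))
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("'width' must be odd and >= 1")
  if (width > sweep_length(rec)) stop("'width' exceeds the sweep length")
  if (width == 1L) return(rec)
  h <- (width - 1L) %/% 2L
  rec$sweeps <- lapply(rec$sweeps, function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(h)]), x, rev(x[(n - h + 1L):n]))
    cs <- c(0, cumsum(xp))
    (cs[(width + 1L):(n + width)] - cs[seq_len(n)]) / width
  })
  rec
}

# reverse Bessel polynomial coefficients, ascending powers:
# theta_n(s) = sum_k a_k s^k, a_k = (2n-k)! / (2^(n-k) k! (n-k)!)
.reverse_bessel_coef <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

# analog prototype: poles (roots of theta_n) scaled so |H(i w)| = 1/sqrt(2)
# at w = 1; gain = prod(-poles) keeps DC gain 1
.bessel_prototype <- function(order) {
  a <- .reverse_bessel_coef(order)
  poles <- polyroot(a)
  magsq <- function(w) {
    s <- 1i * w
    num <- a[1]
    den <- vapply(s, function(si) sum(a * si^(0:order)), complex(1))
    Mod(num / den)^2
  }
  w3 <- stats::uniroot(function(w) magsq(w) - 0.5, c(1e-6, 10 * order + 10),
                       tol = 1e-12)$root
  poles / w3
}

# expand a polynomial from its roots; returns real coefficients,
# descending powers, leading coefficient 1
.poly_from_roots <- function(r) {
  coef <- 1
  for (rt in r) coef <- c(coef, 0) - c(0, coef * rt)
  re <- Re(coef)
  if (max(abs(Im(coef))) > 1e-8 * max(abs(re), 1)) {
    stop("internal error: complex polynomial coefficients")
  }
  re
}

# digital low-pass Bessel via bilinear transform; returns list(b, a)
.bessel_design <- function(order, cutoff_hz, dt_s) {
  p <- .bessel_prototype(order)
  wc <- 2 / dt_s * tan(pi * cutoff_hz * dt_s)   # prewarped analog cutoff
  p <- p * wc
  fs2 <- 2 / dt_s
  zp <- (fs2 + p) / (fs2 - p)                    # bilinear pole map
  a <- .poly_from_roots(zp)
  b <- .poly_from_roots(rep(-1 + 0i, order))     # zeros at z = -1
  b <- b * sum(a) / sum(b)                       # exact unit DC gain
  list(b = b, a = a)
}

# single-pass IIR (direct form I) via stats::filter. The signal level at
# x[1] is subtracted before filtering and restored after, so a signal that
# starts at steady state has no startup transient (DC gain is exactly 1).
.iir_pass <- function(x, b, a) {
  c0 <- x[1]
  x0 <- x - c0
  nb <- length(b)
  xpad <- c(numeric(nb - 1L), x0)
  v <- stats::filter(xpad, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x0) - 1L)]
  y <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(y) + c0
}

.filtfilt <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  # odd reflection extension, as is standard for zero-phase filtering
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(pre, x, post)
  y <- .iir_pass(xp, b, a)
  y <- rev(.iir_pass(rev(y), b, a))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase low-pass Bessel filter
#'
#' Applies an `order`-pole low-pass Bessel filter forward and backward over
#' each sweep, giving zero phase shift (event peaks and onsets are not
#' delayed) at the cost of squaring the magnitude response, i.e. the
#' effective attenuation order is doubled. DC gain is exactly 1. The cutoff
#' is the -3 dB point of a single pass.
#'
#' @param rec A [recording()].
#' @param order Filter order, 1-10.
#' @param cutoff_hz -3 dB cutoff frequency in Hz, below Nyquist.
#' @return The filtered recording.
#' @export
bessel_filter <- function(rec, order = 8L, cutoff_hz) {
  stopifnot(inherits(rec, "recording"))
  order <- as.integer(order)
  if (order < 1L || order > 10L) stop("'order' must be between 1 and 10")
  nyq <- 1 / (2 * rec$dt)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("'cutoff_hz' must lie in (0, Nyquist = ", nyq, " Hz)")
  }
  d <- .bessel_design(order, cutoff_hz, rec$dt)
  pad <- as.integer(min(sweep_length(rec) - 1L,
                        max(3L * order, ceiling(2 / (cutoff_hz * rec$dt)))))
  rec$sweeps <- lapply(rec$sweeps, .filtfilt, b = d$b, a = d$a, pad = pad)
  rec
}

#' Subtract a baseline from every sweep
#'
#' @param rec A [recording()].
#' @param mode `"whole_trace_mean"` subtracts each sweep's own mean;
#'   `"window_mean"` subtracts the mean of the samples in `window` (a
#'   `c(start, end)` time window in seconds, half-open); `"fixed_value"`
#'   subtracts `value`.
#' @param window Time window for `window_mean`.
#' @param value Scalar for `fixed_value`.
#' @return The baseline-subtracted recording.
#' @export
subtract_baseline <- function(rec,
                              mode = c("whole_trace_mean", "window_mean", "fixed_value"),
                              window = NULL, value = NULL) {
  stopifnot(inherits(rec, "recording"))
  mode <- match.arg(mode)
  rec$sweeps <- switch(mode,
    whole_trace_mean = lapply(rec$sweeps, function(x) x - mean(x)),
    window_mean = {
      if (is.null(window) || length(window) != 2L) {
        stop("'window' (start, end in seconds) is required for window_mean")
      }
      lapply(seq_len(n_sweeps(rec)), function(sw) {
        sl <- slice_recording(rec, window[1], window[2], sw)
        if (length(sl$samples) == 0L) stop("baseline window contains no samples")
        rec$sweeps[[sw]] - mean(sl$samples)
      })
    },
    fixed_value = {
      if (is.null(value)) stop("'value' is required for fixed_value")
      lapply(rec$sweeps, function(x) x - value)
    })
  rec
}

#' Average all sweeps of a recording
#'
#' Pointwise mean across sweeps, intended for pre-aligned evoked responses;
#' no attempt is made to align the traces in time. Averaging N sweeps
#' reduces independent noise by about `1/sqrt(N)`.
#'
#' @param rec A [recording()].
#' @return A single-sweep [recording()] with unchanged `dt`.
#' @export
average_sweeps <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  avg <- Reduce(`+`, rec$sweeps) / n_sweeps(rec)
  recording(avg, dt = rec$dt, unit_label = rec$unit_label, t0 = rec$t0)
}
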