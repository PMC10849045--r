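#' Per-sweep extrema statistics for evoked responses
#'
#' Computes the minimum and maximum data point of each sweep (optionally
#' restricted to a time window) and reports the mean and sample standard
#' deviation (denominator N-1) of the minima and of the maxima across
#' sweeps. With a single sweep, sds are reported as 0 and flagged.
#'
#' @param rec A [recording()].
#' @param window Optional `c(start, end)` time window in seconds (half-open);
#'   default is the whole sweep.
#' @return An object of class `evoked_summary`: a list with `per_sweep_min`,
#'   `per_sweep_max`, `mean_min`, `sd_min`, `mean_max`, `sd_max`,
#'   `single_sweep`.
#' @examples
#' rec <- recording(list(c(0, 1, 2), c(0, 2, 4)), dt = 1e-4)
#' sweep_extrema(rec)
#' @export
sweep_extrema <- function(rec, window = NULL) {
  stopifnot(inherits(rec, "recording"))
  vals <- lapply(seq_len(n_sweeps(rec)), function(sw) {
    if (is.null(window)) {
      rec$sweeps[[sw]]
    } else {
      sl <- slice_recording(rec, window[1], window[2], sw)
      if (length(sl$samples) == 0L) stop("window contains no samples")
      sl$samples
    }
  })
  mins <- vapply(vals, min, numeric(1))
  maxs <- vapply(vals, max, numeric(1))
  single <- length(mins) == 1L
  structure(list(
    per_sweep_min = mins, per_sweep_max = maxs,
    mean_min = mean(mins), sd_min = if (single) 0 else stats::sd(mins),
    mean_max = mean(maxs), sd_max = if (single) 0 else stats::sd(maxs),
    single_sweep = single
  ), class = "evoked_summary")
}

#' @export
print.evoked_summary <- function(x, ...) {
  cat(sprintf("<evoked_summary> %d sweep(s)%s\n", length(x$per_sweep_min),
              if (x$single_sweep) " [single sweep: sd = 0]" else ""))
  cat(sprintf("  min: mean = %g, sd = %g\n", x$mean_min, x$sd_min))
  cat(sprintf("  max: mean = %g, sd = %g\n", x$mean_max, x$sd_max))
  invisible(x)
}
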