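#' Construct a recording
#'
#' A `recording` is the core container of the package: a uniformly sampled,
#' possibly multi-sweep time series (current or potential). All sweeps share
#' one sampling interval `dt` and one unit label; the time of sample `i`
#' (1-based) of any sweep is `t0 + (i - 1) * dt`. Time values are never
#' stored, only generated on demand.
#'
#' @param sweeps A numeric vector (one sweep), a list of equal-length numeric
#'   vectors, or a numeric matrix with one column per sweep.
#' @param dt Sampling interval in seconds per sample. Must be positive.
#' @param unit_label Unit of the samples, carried as a label only (e.g.
#'   `"pA"`, `"nA"`, `"mV"`); no conversion is ever performed.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `recording`: a list with elements `sweeps`
#'   (list of numeric vectors), `dt`, `unit_label`, `t0`.
#' @examples
#' rec <- recording(c(0, 1, 0), dt = 1e-4)
#' rec_times(rec)
#' @export
recording <- function(sweeps, dt, unit_label = "pA", t0 = 0) {
  if (is.matrix(sweeps)) {
    sweeps <- lapply(seq_len(ncol(sweeps)), function(j) as.numeric(sweeps[, j]))
  } else if (is.numeric(sweeps)) {
    sweeps <- list(as.numeric(sweeps))
  } else if (is.list(sweeps)) {
    sweeps <- lapply(sweeps, as.numeric)
  } else {
    stop("'sweeps' must be a numeric vector, list of vectors, or matrix")
  }
  if (length(sweeps) < 1L) stop("a recording needs at least one sweep")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number (seconds per sample)")
  }
  lens <- vapply(sweeps, length, integer(1))
  if (any(lens < 2L)) stop("every sweep must contain at least 2 samples")
  if (length(unique(lens)) != 1L) {
    stop("all sweeps must have identical length (got ",
         paste(unique(lens), collapse = ", "), ")")
  }
  structure(
    list(sweeps = sweeps, dt = as.numeric(dt),
         unit_label = as.character(unit_label)[1], t0 = as.numeric(t0)[1]),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  n <- sweep_length(x)
  cat(sprintf(
    "<recording> %d sweep(s) x %d samples, dt = %g s (%.6g kHz), unit = %s\n",
    n_sweeps(x), n, x$dt, 1e-3 / x$dt, x$unit_label))
  cat(sprintf("  time span: [%g, %g] s\n", x$t0, x$t0 + (n - 1) * x$dt))
  invisible(x)
}

#' Number of sweeps in a recording
#' @param rec A [recording()].
#' @return Integer count of sweeps.
#' @export
n_sweeps <- function(rec) length(rec$sweeps)

#' Number of samples per sweep
#' @param rec A [recording()].
#' @return Integer sweep length.
#' @export
sweep_length <- function(rec) length(rec$sweeps[[1]])

#' Sample times of a recording
#'
#' @param rec A [recording()].
#' @return Numeric vector of times in seconds, `t0 + (0:(n-1)) * dt`.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(sweep_length(rec)) - 1) * rec$dt

#' Extract the samples inside a time window
#'
#' Windows are half-open: a sample whose time equals `end` is excluded. This
#' avoids double-counting samples at the seams of adjacent windows during
#' scanning.
#'
#' @param rec A [recording()].
#' @param start,end Window bounds in seconds, `start < end`.
#' @param sweep Sweep index (1-based, default 1).
#' @return A list with `samples` (numeric, possibly empty) and `first_index`,
#'   the 1-based index in the sweep of the first returned sample (`NA` when
#'   the overlap is empty).
#' @export
slice_recording <- function(rec, start, end, sweep = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(start) || !is.numeric(end) || start >= end) {
    stop("'start' must be < 'end'")
  }
  if (sweep < 1L || sweep > n_sweeps(rec)) {
    stop("sweep index out of range (1..", n_sweeps(rec), ")")
  }
  n <- sweep_length(rec)
  # first index i with t0 + (i-1) dt >= start; last with time < end
  i0 <- max(1L, as.integer(ceiling((start - rec$t0) / rec$dt - 1e-9)) + 1L)
  i1 <- min(n, as.integer(ceiling((end - rec$t0) / rec$dt - 1e-9)))
  if (i0 > i1) return(list(samples = numeric(0), first_index = NA_integer_))
  list(samples = rec$sweeps[[sweep]][i0:i1], first_index = i0)
}

#' Read a recording from a CSV file
#'
#' The canonical dialect is one numeric column per sweep, comma-separated,
#' dot decimal, with an optional single header row (detected automatically:
#' if the first row is not fully numeric it is treated as a header). The CSV
#' stores no sampling rate, so `dt` is supplied by the caller. As a
#' convenience, a two-column `time,value` file (first header cell `"time"`)
#' is accepted; the time column is dropped.
#'
#' @param path Path to an existing CSV file.
#' @param dt Sampling interval in seconds per sample.
#' @param unit_label Unit label for the samples.
#' @return A [recording()] with sweeps in column order.
#' @export
read_recording_csv <- function(path, dt, unit_label = "pA") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty CSV file: ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncol0 <- length(rows[[1]])
  as_num <- function(cells) suppressWarnings(as.numeric(trimws(cells)))
  first <- as_num(rows[[1]])
  has_header <- anyNA(first)
  drop_time <- FALSE
  if (has_header) {
    if (tolower(trimws(rows[[1]][1])) == "time" && ncol0 >= 2L) drop_time <- TRUE
    rows <- rows[-1]
    if (length(rows) == 0L) stop("CSV contains a header but no data: ", path)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L || lens[1] != ncol0) {
    bad <- which(lens != ncol0)[1]
    stop("ragged CSV: row ", bad + has_header, " has ", lens[bad],
         " columns, expected ", ncol0)
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol0)
  for (i in seq_along(rows)) {
    v <- as_num(rows[[i]])
    if (anyNA(v)) {
      stop("non-numeric value in data row ", i + has_header, " of ", path)
    }
    mat[i, ] <- v
  }
  if (drop_time) mat <- mat[, -1, drop = FALSE]
  recording(mat, dt = dt, unit_label = unit_label)
}

#' Write a recording to a CSV file
#'
#' One column per sweep, full double precision (17 significant digits), with
#' a `sweep_<k>` header row. Round-trips through [read_recording_csv()]
#' bit-exactly.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$sweeps) == 0L) stop("recording has no sweeps; refusing to write an empty file")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(sprintf("sweep_%d", seq_len(n_sweeps(rec))), collapse = ","), con)
  cols <- lapply(rec$sweeps, function(x) sprintf("%.17g", x))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}
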