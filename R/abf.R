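# Minimal Axon Binary Format (ABF) version-1 reader.
#
# Only the subset of the ABF1 header needed to materialize one analog input
# channel is parsed: acquisition length, episode (sweep) count, per-channel
# sampling interval, data format (16-bit integer with instrument scaling, or
# 4-byte float), data section pointer, and per-channel unit strings. ABF2
# files are rejected with an informative error. ABF writing is out of scope.

.abf1_header_offsets <- list(
  signature            = list(at = 0L,   what = "char", n = 4L),
  fFileVersionNumber   = list(at = 4L,   what = "float", n = 1L),
  nOperationMode       = list(at = 8L,   what = "int16", n = 1L),
  lActualAcqLength     = list(at = 10L,  what = "int32", n = 1L),
  lActualEpisodes      = list(at = 16L,  what = "int32", n = 1L),
  lDataSectionPtr      = list(at = 40L,  what = "int32", n = 1L),
  nDataFormat          = list(at = 100L, what = "int16", n = 1L),
  nADCNumChannels      = list(at = 120L, what = "int16", n = 1L),
  fADCSampleInterval   = list(at = 122L, what = "float", n = 1L),
  fADCRange            = list(at = 244L, what = "float", n = 1L),
  lADCResolution       = list(at = 252L, what = "int32", n = 1L),
  sADCUnits            = list(at = 602L, what = "char", n = 128L),
  fADCProgrammableGain = list(at = 730L, what = "float", n = 16L),
  fInstrumentScaleFactor = list(at = 922L, what = "float", n = 16L),
  fInstrumentOffset    = list(at = 986L, what = "float", n = 16L)
)

.read_abf1_field <- function(con, field) {
  seek(con, where = field$at, origin = "start")
  switch(field$what,
    char  = rawToChar(readBin(con, "raw", n = field$n)),
    int16 = readBin(con, "integer", n = field$n, size = 2L, endian = "little"),
    int32 = readBin(con, "integer", n = field$n, size = 4L, endian = "little"),
    float = readBin(con, "numeric", n = field$n, size = 4L, endian = "little"))
}

#' Read one channel of an Axon Binary Format (ABF v1) file
#'
#' Parses the ABF1 binary layout directly (no external parser is required).
#' Exactly one channel is materialized per call, since event detection
#' operates on a single signal. The sampling interval is taken from the file
#' header (`fADCSampleInterval`, microseconds per channel sample, times the
#' channel count for interleaved acquisition) and the unit label from the
#' channel's `sADCUnits` entry. Both 16-bit integer data (rescaled by the
#' instrument gain/offset fields) and 4-byte float data are supported.
#'
#' @param path Path to an ABF v1 file.
#' @param channel 1-based analog input channel index.
#' @return A [recording()]; episodic files yield one sweep per episode.
#' @export
read_abf <- function(path, channel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  h <- lapply(.abf1_header_offsets, .read_abf1_field, con = con)
  if (identical(substr(h$signature, 1, 4), "ABF2")) {
    stop("ABF2 files are not supported by this reader (ABF v1 only)")
  }
  if (!identical(substr(h$signature, 1, 3), "ABF")) {
    stop("not an ABF file (bad signature): ", path)
  }
  n_chan <- h$nADCNumChannels
  if (n_chan < 1L) stop("ABF header reports no ADC channels")
  units <- vapply(seq_len(n_chan), function(k) {
    trimws(substr(h$sADCUnits, (k - 1L) * 8L + 1L, k * 8L))
  }, character(1))
  if (channel < 1L || channel > n_chan) {
    stop("channel ", channel, " not present; available channels: ",
         paste(sprintf("%d (%s)", seq_len(n_chan), units), collapse = ", "))
  }
  n_total <- h$lActualAcqLength
  if (n_total < 1L) stop("ABF header reports no data")
  seek(con, where = h$lDataSectionPtr * 512L, origin = "start")
  if (h$nDataFormat == 0L) {
    raw16 <- readBin(con, "integer", n = n_total, size = 2L, endian = "little")
    scale <- h$fADCRange / h$lADCResolution /
      (h$fInstrumentScaleFactor[channel] * h$fADCProgrammableGain[channel])
    vals_all <- raw16 * scale + h$fInstrumentOffset[channel]
  } else if (h$nDataFormat == 1L) {
    vals_all <- readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
  } else {
    stop("unsupported ABF data format code: ", h$nDataFormat)
  }
  # channels are interleaved sample-by-sample
  vals <- vals_all[seq(channel, n_total, by = n_chan)]
  n_sw <- max(1L, h$lActualEpisodes)
  per_sweep <- length(vals) %/% n_sw
  if (per_sweep * n_sw != length(vals)) {
    stop("ABF data length is not divisible by the episode count")
  }
  sweeps <- split(vals[seq_len(per_sweep * n_sw)],
                  rep(seq_len(n_sw), each = per_sweep))
  dt <- h$fADCSampleInterval * n_chan * 1e-6
  if (!is.finite(dt) || dt <= 0) stop("ABF header has a non-positive sampling interval")
  recording(unname(sweeps), dt = dt,
            unit_label = if (nzchar(units[channel])) units[channel] else "AU")
}
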