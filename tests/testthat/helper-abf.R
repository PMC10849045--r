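# Test-only writer for a synthetic ABF v1 file (the minimal header subset
# the package reader understands). No real acquisition software output is
# available offline, so reader tests are round-trips against this writer;
# the files it produces are synthetic stand-ins for AxoClamp/pClamp output.
write_synthetic_abf1 <- function(path, sweeps_by_channel, dt_s,
                                 units = rep("pA", length(sweeps_by_channel)),
                                 data_format = c("float", "int16")) {
  data_format <- match.arg(data_format)
  n_chan <- length(sweeps_by_channel)
  n_sweeps <- length(sweeps_by_channel[[1]])
  per_sweep <- length(sweeps_by_channel[[1]][[1]])
  header <- raw(2048)
  poke <- function(at, bytes) {
    header[(at + 1):(at + length(bytes))] <<- bytes
  }
  poke(0, charToRaw("ABF "))
  poke(4, writeBin(1.83, raw(), size = 4, endian = "little"))
  poke(8, writeBin(5L, raw(), size = 2, endian = "little"))     # episodic
  n_total <- n_chan * n_sweeps * per_sweep
  poke(10, writeBin(as.integer(n_total), raw(), size = 4, endian = "little"))
  poke(16, writeBin(as.integer(n_sweeps), raw(), size = 4, endian = "little"))
  poke(40, writeBin(4L, raw(), size = 4, endian = "little"))    # data at block 4
  poke(100, writeBin(if (data_format == "float") 1L else 0L, raw(),
                     size = 2, endian = "little"))
  poke(120, writeBin(as.integer(n_chan), raw(), size = 2, endian = "little"))
  poke(122, writeBin(dt_s * 1e6 / n_chan, raw(), size = 4, endian = "little"))
  adc_range <- 10
  adc_res <- 32768L
  poke(244, writeBin(adc_range, raw(), size = 4, endian = "little"))
  poke(252, writeBin(adc_res, raw(), size = 4, endian = "little"))
  unit_block <- vapply(seq_len(16), function(k) {
    u <- if (k <= n_chan) units[k] else ""
    formatC(u, width = 8, flag = "-")
  }, character(1))
  poke(602, charToRaw(paste(unit_block, collapse = "")))
  poke(730, writeBin(rep(1, 16), raw(), size = 4, endian = "little"))
  poke(922, writeBin(rep(1, 16), raw(), size = 4, endian = "little"))
  poke(986, writeBin(rep(0, 16), raw(), size = 4, endian = "little"))

  # interleave channels sample by sample, sweeps concatenated
  flat <- numeric(n_total)
  for (ch in seq_len(n_chan)) {
    all_sw <- unlist(sweeps_by_channel[[ch]], use.names = FALSE)
    flat[seq(ch, n_total, by = n_chan)] <- all_sw
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(header, con)
  if (data_format == "float") {
    writeBin(flat, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(flat / (adc_range / adc_res))), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
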