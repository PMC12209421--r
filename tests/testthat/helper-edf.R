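# Independent minimal EDF/BDF writer used as the oracle for the readers:
# composes the published byte layout directly (256-byte ASCII header,
# 256 bytes per signal, int16 LE / int24 LE data records).

write_edf_fixture <- function(path, samples, fs, labels, bdf = FALSE,
                              pmin = -1000, pmax = 1000) {
  C <- nrow(samples); Tn <- ncol(samples)
  stopifnot(Tn %% fs == 0)
  n_rec <- Tn / fs
  pmin <- rep(pmin, C); pmax <- rep(pmax, C)
  dmin <- if (bdf) -8388608 else -32768
  dmax <- if (bdf) 8388607 else 32767
  pad <- function(x, w) sprintf("%-*s", w, substr(as.character(x), 1, w))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bdf) {
    writeBin(as.raw(255), con)
    writeChar("BIOSEMI", con, 7, eos = NULL)
  } else writeChar(pad("0", 8), con, 8, eos = NULL)
  writeChar(pad("patient", 80), con, 80, eos = NULL)
  writeChar(pad("recording", 80), con, 80, eos = NULL)
  writeChar(pad("01.01.20", 8), con, 8, eos = NULL)
  writeChar(pad("00.00.00", 8), con, 8, eos = NULL)
  writeChar(pad(256 * (1 + C), 8), con, 8, eos = NULL)
  writeChar(pad("", 44), con, 44, eos = NULL)
  writeChar(pad(n_rec, 8), con, 8, eos = NULL)
  writeChar(pad("1", 8), con, 8, eos = NULL)
  writeChar(pad(C, 4), con, 4, eos = NULL)
  wfld <- function(vals, w)
    for (v in vals) writeChar(pad(v, w), con, w, eos = NULL)
  wfld(labels, 16); wfld(rep("", C), 80); wfld(rep("uV", C), 8)
  wfld(pmin, 8); wfld(pmax, 8); wfld(rep(dmin, C), 8); wfld(rep(dmax, C), 8)
  wfld(rep("", C), 80); wfld(rep(fs, C), 8); wfld(rep("", C), 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((samples - pmin) * scale + dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(C)) {
      v <- as.integer(dig[s, ((r - 1) * fs + 1):(r * fs)])
      if (bdf) {
        vv <- ifelse(v < 0, v + 16777216, v)
        b <- rbind(vv %% 256, (vv %/% 256) %% 256, (vv %/% 65536) %% 256)
        writeBin(as.raw(as.vector(b)), con)
      } else writeBin(v, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
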