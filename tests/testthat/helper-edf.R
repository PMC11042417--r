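# Byte-level EDF writer used to exercise the package's EDF reader.

write_edf_fixture <- function(path, data, fs, labels = NULL) {
  ns <- nrow(data)
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(ns))
  n_samp <- ncol(data)
  rec_dur <- 1
  spr <- fs * rec_dur
  n_rec <- n_samp / spr
  stopifnot(n_rec == round(n_rec))
  pmin_ <- apply(data, 1, min) - 1e-6
  pmax_ <- apply(data, 1, max) + 1e-6
  dmin_ <- -32768; dmax_ <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44)
  wr(n_rec, 8); wr(format(rec_dur), 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("synthetic", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(format(pmin_[i], digits = 6), 8)
  for (i in 1:ns) wr(format(pmax_[i], digits = 6), 8)
  for (i in 1:ns) wr(dmin_, 8)
  for (i in 1:ns) wr(dmax_, 8)
  for (i in 1:ns) wr("none", 80)
  for (i in 1:ns) wr(spr, 8)
  for (i in 1:ns) wr("", 32)
  for (r in seq_len(n_rec)) for (s in seq_len(ns)) {
    seg <- data[s, ((r - 1) * spr + 1):(r * spr)]
    dig <- round(dmin_ + (seg - pmin_[s]) * (dmax_ - dmin_) /
                   (pmax_[s] - pmin_[s]))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
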