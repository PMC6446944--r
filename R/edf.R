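#' Minimal EDF reader and writer
#'
#' Plain EDF (16-bit integer samples, fixed-format ASCII header), with
#' one-second data records and per-channel physical scaling honoured.
#' Covers the subset of the format needed to exchange continuous
#' multichannel recordings; EDF+ annotations and discontinuous files are
#' out of scope. Padded (`NA`) samples cannot be represented in EDF and
#' are written as the physical value 0 with a warning.
#'
#' @param rec A `recording` whose sampling rate is a whole number.
#' @param path File path.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns a
#'   `recording`.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs %% 1 != 0) stopf("EDF writer needs an integer sampling rate")
  data <- rec$data
  if (anyNA(data)) {
    warning("EDF cannot store missing samples; writing them as 0")
    data[is.na(data)] <- 0
  }
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)), con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(pad(vals, w), collapse = ""),
                                     con, eos = NULL)
  fld(substr(rec$labels, 1, 16), 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, format = "g", digits = 6), 8)
  fld(formatC(pmax_, format = "g", digits = 6), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  # re-read the header's own (ASCII-rounded) physical extrema so that
  # write -> read round-trips within one quantization step
  pmin_h <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_h <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((data[i, idx] - pmin_h[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                 # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)         # transducer
  for (i in seq_len(ns)) rd(8)          # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)         # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin[i]) * gain[i] + pmin_[i]
    }
  }
  recording(data, spr[1] / rec_dur, labels)
}
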