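# Minimal European Data Format (EDF) support: 16-bit continuous signals,
# one data record. Covers what this package writes; not a general EDF library.

fmt_field <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1, width)
}

#' Write a recording as EDF
#'
#' Single-data-record EDF with per-channel physical scaling over the 16-bit
#' digital range. Quantization error is bounded by (max - min) / 65535 per
#' channel.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  ns <- nrow(sig)
  nsamp <- ncol(sig)
  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fmt_field("0", 8), fmt_field("synthetic subject", 80),
    fmt_field("anxeeg export", 80),
    fmt_field("01.01.00", 8), fmt_field("00.00.00", 8),
    fmt_field(256 * (ns + 1), 8), fmt_field("", 44),
    fmt_field(1, 8), fmt_field(format(nsamp / recording$sampling_rate), 8),
    fmt_field(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(recording$channel_names, fmt_field, "", 16), collapse = ""),
    paste(rep(fmt_field("", 80), ns), collapse = ""),
    paste(rep(fmt_field("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin), fmt_field, "", 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax), fmt_field, "", 8), collapse = ""),
    paste(rep(fmt_field(-32768, 8), ns), collapse = ""),
    paste(rep(fmt_field(32767, 8), ns), collapse = ""),
    paste(rep(fmt_field("", 80), ns), collapse = ""),
    paste(rep(fmt_field(nsamp, 8), ns), collapse = ""),
    paste(rep(fmt_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  # re-read header values to guarantee write/read scaling symmetry
  pmin_r <- as.numeric(sprintf("%.6g", pmin))
  pmax_r <- as.numeric(sprintf("%.6g", pmax))
  for (i in seq_len(ns)) {
    dig <- round((sig[i, ] - pmin_r[i]) / (pmax_r[i] - pmin_r[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples), `sampling_rate`,
#'   `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (ver != "0") stop(sprintf("not an EDF file: %s", path), call. = FALSE)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  sig <- matrix(0, ns, nsamp[1] * n_rec, dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
      sig[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
    }
  }
  list(signal = sig, sampling_rate = nsamp[1] / rec_dur, channel_names = labels)
}
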