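# Minimal EDF (European Data Format) reader/writer for interoperability.
# 16-bit EDF with one-second data records; cue events travel in a sidecar
# CSV (`<file>.events.csv`, columns sample,label) since plain EDF has no
# annotation channel. Rejected trials may be marked with label -1.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with 1-s records; each channel is scaled to its own physical
#' range. The signal is zero-padded to a whole number of records. Events are
#' written to `<file>.events.csv`.
#'
#' @param rec a [raw_recording()]; `sfreq` must be an integer.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_edf <- function(rec, file) {
  stopifnot(inherits(rec, "raw_recording"))
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9) stop("EDF export needs an integer sfreq")
  sf <- as.integer(round(sf))
  nc <- nrow(rec$signal)
  n_rec <- ceiling(ncol(rec$signal) / sf)
  sig <- matrix(0, nc, n_rec * sf)
  sig[, seq_len(ncol(rec$signal))] <- rec$signal

  # symmetric integer physical range per channel: exactly representable in
  # the 8-character ASCII header fields, so no precision is lost to rounding
  M <- pmax(ceiling(apply(abs(sig), 1, max)), 1)
  pmin_ <- -M; pmax_ <- M
  dmin <- -32768; dmax <- 32767

  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field("synthetic", 80),
                pad_field("lrpselect export", 80),
                pad_field("01.01.00", 8), pad_field("00.00.00", 8),
                pad_field(256 + 256 * nc, 8), pad_field("", 44),
                pad_field(n_rec, 8), pad_field(1, 8), pad_field(nc, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(c(rec$channel_names, 16), c(rep("", nc), 80),
                 c(rep("uV", nc), 8),
                 c(formatC(pmin_, format = "d"), 8),
                 c(formatC(pmax_, format = "d"), 8),
                 c(rep(dmin, nc), 8), c(rep(dmax, nc), 8),
                 c(rep("", nc), 80), c(rep(sf, nc), 8), c(rep("", nc), 32))
  for (f in fields) {
    w <- as.integer(f[length(f)])
    vals <- f[-length(f)]
    writeChar(paste0(vapply(vals, pad_field, "", width = w), collapse = ""),
              con, eos = NULL)
  }
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * sf + seq_len(sf)
    for (c in seq_len(nc)) {
      dig <- round((sig[c, cols] - pmin_[c]) * scale[c] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  if (nrow(rec$events) > 0)
    utils::write.csv(rec$events, paste0(file, ".events.csv"),
                     row.names = FALSE)
  invisible(file)
}

#' Read an EDF file
#'
#' Supports plain 16-bit EDF. If `<file>.events.csv` exists its (sample,
#' label) rows become the recording's events; rows with label -1 (rejected
#' trials) are excluded with a message.
#'
#' @param file path to the EDF file.
#' @return A [raw_recording()].
#' @export
read_edf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  rd(80 * nc)
  rd(8 * nc)                  # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(32 * nc)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  sf <- spr[1] / dur
  sig <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * spr[1] + seq_len(spr[1])
    for (c in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      sig[c, cols] <- (dig - dmin[c]) * (pmax_[c] - pmin_[c]) /
        (dmax[c] - dmin[c]) + pmin_[c]
    }
  }
  events <- data.frame(sample = integer(0), label = integer(0))
  evf <- paste0(file, ".events.csv")
  if (file.exists(evf)) {
    events <- utils::read.csv(evf)
    rej <- events$label < 0
    if (any(rej)) {
      message(sum(rej), " rejected trial(s) excluded")
      events <- events[!rej, , drop = FALSE]
    }
  }
  raw_recording(sig, sf, events, labels)
}
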