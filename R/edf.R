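## Minimal EDF (European Data Format) writer/reader for a single
## continuous channel, 16-bit samples. Implemented in-package because no
## EDF support is available among the installed R packages; covers the
## standard fixed-layout header and honors the physical dimension on read.

.edf_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, s)
}

#' Write a single-channel EDF file
#'
#' Standard EDF: 256-byte global header, one 256-byte signal header, and
#' data records of 16-bit little-endian integers. Samples are linearly
#' quantized between the physical min/max of the data. The signal is
#' truncated to a whole number of data records (logged).
#'
#' @param path output path.
#' @param x numeric samples.
#' @param fs sample rate (Hz); `fs * record_duration_s` must be integer.
#' @param label signal label (16 chars max).
#' @param physical_dim physical dimension string, e.g. `"uV"` or `"mV"`.
#' @param record_duration_s duration of one data record (s).
#' @return invisibly, `path`.
#' @export
write_edf <- function(path, x, fs, label = "EEG Fp",
                      physical_dim = "uV", record_duration_s = 1) {
  spr <- fs * record_duration_s
  if (abs(spr - round(spr)) > 1e-9)
    stop("fs * record_duration_s must be an integer number of samples")
  spr <- as.integer(round(spr))
  n_rec <- length(x) %/% spr
  if (n_rec < 1) stop("signal shorter than one data record")
  if (n_rec * spr < length(x))
    message(sprintf("write_edf: truncating %d trailing samples (whole records only)",
                    length(x) - n_rec * spr))
  x <- x[seq_len(n_rec * spr)]

  pmax_ <- max(abs(range(x)), 1e-6)
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32767L; dig_max <- 32767L
  dig <- as.integer(round((x - phys_min) / (phys_max - phys_min) *
                            (dig_max - dig_min) + dig_min))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8), .edf_field("X X X X", 80), .edf_field("Startdate X", 80),
    .edf_field("01.01.00", 8), .edf_field("00.00.00", 8),
    .edf_field(256 + 256, 8), .edf_field("", 44),
    .edf_field(n_rec, 8), .edf_field(format(record_duration_s), 8),
    .edf_field(1, 4),
    ## signal header (one signal)
    .edf_field(label, 16), .edf_field("", 80), .edf_field(physical_dim, 8),
    .edf_field(format(phys_min, digits = 7), 8),
    .edf_field(format(phys_max, digits = 7), 8),
    .edf_field(dig_min, 8), .edf_field(dig_max, 8),
    .edf_field("BP:0.5-47Hz", 80), .edf_field(spr, 8), .edf_field("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Parses the standard header, reads the 16-bit samples of the first
#' signal and rescales them to physical units. If the physical dimension
#' is `mV` or `V` the samples are converted to uV.
#'
#' @param path EDF file path.
#' @return list with `data` (uV if the dimension was a voltage), `fs`,
#'   `label`, `unit` (the unit of `data` after conversion) and
#'   `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns < 1) stop("EDF file contains no signals")
  lab <- character(ns); pdim <- character(ns)
  pmin <- pmax_ <- dmin <- dmax <- numeric(ns); spr <- integer(ns)
  f <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  lab <- f(16); f(80); pdim <- f(8)
  pmin <- as.numeric(f(8)); pmax_ <- as.numeric(f(8))
  dmin <- as.numeric(f(8)); dmax <- as.numeric(f(8))
  f(80); spr <- as.integer(f(8)); f(32)
  seek(con, header_bytes)

  total_per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * total_per_rec, size = 2,
                 signed = TRUE, endian = "little")
  ## de-interleave signal 1 from each record
  idx <- as.vector(outer(seq_len(spr[1]), (seq_len(n_rec) - 1) * total_per_rec, `+`))
  dig <- raw[idx]
  phys <- pmin[1] + (dig - dmin[1]) * (pmax_[1] - pmin[1]) / (dmax[1] - dmin[1])
  scale <- switch(tolower(pdim[1]), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1)
  list(data = phys * scale, fs = spr[1] / rec_dur, label = lab[1],
       unit = if (scale != 1 || tolower(pdim[1]) %in% c("uv", "µv")) "uV" else pdim[1],
       n_records = n_rec)
}
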