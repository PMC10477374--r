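# Minimal EDF (European Data Format) reader/writer: 16-bit integer data
# records with per-signal linear calibration, as produced by clinical EEG
# amplifiers. Continuous recordings only (EDF, not EDF+D).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)                      # left-aligned, space padded
}

#' Write a recording to an EDF file
#'
#' Each channel is scaled to the full 16-bit digital range using its own
#' physical min/max, so the round-trip quantization error is at most one
#' digital step.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param record_duration Data record length in seconds (default 1). Samples
#'   beyond the last whole record are dropped.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1,
                      patient = "X", recording = "synthetic") {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  ns <- nrow(data)
  spr <- as.integer(rec$rate * record_duration)
  n_rec <- ncol(data) %/% spr
  if (n_rec < 1) stop("recording shorter than one data record")
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_duration), 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(signif(pmin_, 7), edf_pad, "", width = 8),
    vapply(signif(pmax_, 7), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
  # re-read the printed physical limits so the calibration used for encoding
  # matches what a reader will parse from the header
  pmin_h <- as.numeric(vapply(signif(pmin_, 7), edf_pad, "", width = 8))
  pmax_h <- as.numeric(vapply(signif(pmax_, 7), edf_pad, "", width = 8))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - pmin_h[ch]) * gain[ch]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the header, validates the record structure against the actual file
#' size, and returns calibrated data in physical units (µV). Channels named
#' A1/A2 (ear references) or VEOU/VEOL/HEOR/HEOL (EOG) are retained but
#' flagged as non-scalp.
#'
#' @param path EDF file path.
#' @param positions Optional label -> 3-D coordinate table (see
#'   [load_montage()]); defaults to the packaged 10--20 montage for labels it
#'   covers.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, positions = NULL) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256) stop("not an EDF file (shorter than one header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) readChar(con, nchars, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop("unsupported EDF version field at offset 0: '", version, "'")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed header: bad signal count at offset 252")
  if (hdr_bytes != 256 * (ns + 1))
    stop("malformed header: header size field ", hdr_bytes,
         " != 256*(ns+1) = ", 256 * (ns + 1))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)                       # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                       # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mismatched samples-per-record across channels: ", paste(spr, collapse = ","))
  rec_bytes <- sum(spr) * 2
  avail <- (size - hdr_bytes) / rec_bytes
  if (avail < n_rec)
    stop("truncated file: header declares ", n_rec, " data records but only ",
         floor(avail), " are present (", size, " bytes)")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0.0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  rate <- spr[1] / rec_dur
  if (is.null(positions)) {
    mon <- load_montage()
    have <- labels %in% mon$label
    if (any(have)) {
      positions <- as.matrix(mon[match(labels[have], mon$label), c("x_mm", "y_mm", "z_mm")])
      rownames(positions) <- labels[have]
    }
  }
  eeg_recording(data, channels = labels, rate = rate, positions = positions)
}
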