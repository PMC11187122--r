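# Minimal EDF (European Data Format, 16-bit) writer and reader.
# Supports what the pipeline needs: equal sampling rate across channels,
# 1-second data records, physical min/max taken from the data range.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

num_field <- function(x, width) {
  s <- formatC(x, digits = 7, format = "g", width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a multichannel recording to an EDF file
#'
#' Physical min/max are set per channel from the data range; samples are
#' quantised to 16-bit integers, so a round trip reproduces the signal to
#' within one quantisation step `(pmax - pmin) / 65535`.
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz (samples per 1-second data record).
#' @param path Output file path.
#' @param channel_names Channel labels (default EEG1..EEGn).
#' @param patient_id,recording_id Header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, fs, path, channel_names = NULL,
                      patient_id = "X", recording_id = "Startdate X") {
  stopifnot(is.matrix(signal), fs > 0)
  nc <- nrow(signal)
  if (is.null(channel_names)) channel_names <- paste0("EEG", seq_len(nc))
  fs <- as.integer(round(fs))
  n <- ncol(signal)
  n_rec <- ceiling(n / fs)
  if (n < n_rec * fs) {  # zero-pad the trailing partial record
    signal <- cbind(signal, matrix(0, nc, n_rec * fs - n))
  }
  pmin_ <- apply(signal, 1, min)
  pmax_ <- apply(signal, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(patient_id, 80),
    pad_field(recording_id, 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 + 256 * nc, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(nc, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(channel_names, pad_field, "", width = 16), collapse = ""),
    strrep(pad_field("", 80), nc),
    strrep(pad_field("uV", 8), nc),
    paste(vapply(pmin_, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", width = 8), collapse = ""),
    strrep(pad_field(dmin, 8), nc),
    strrep(pad_field(dmax, 8), nc),
    strrep(pad_field("", 80), nc),
    strrep(pad_field(fs, 8), nc),
    strrep(pad_field("", 32), nc)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * fs + seq_len(fs)
    block <- signal[, cols, drop = FALSE]
    dig <- round((block - pmin_) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    # records hold each channel's samples contiguously
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with `signal` (channels x samples, physical units), `fs`,
#'   `channel_names`, `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  rdn <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8))
  pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8))
  dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))                # samples per record, per channel
  rdn(32)
  if (length(unique(spr)) != 1L) stop("unequal per-channel sampling rates")
  fs <- spr[1] / rec_dur

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  dig <- array(raw, c(spr[1], nc, n_rec))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  signal <- matrix(0, nc, n_rec * spr[1])
  for (ch in seq_len(nc)) {
    signal[ch, ] <- as.vector(dig[, ch, ]) * scale[ch] +
      (pmin_[ch] - dmin[ch] * scale[ch])
  }
  list(signal = signal, fs = fs, channel_names = labels, n_records = n_rec)
}
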