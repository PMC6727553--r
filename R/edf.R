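# Minimal European Data Format (EDF) support: continuous recordings, 16-bit
# integer samples, one data-record duration shared by all signals. Covers what
# a two-channel EEG+EMG sleep recording needs; no annotations, no EDF+.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "fg")
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a declared physical range
#' (defaults span the amplitudes seen in rodent polysomnography with
#' headroom). Each channel is written at its native rate with a 1-second data
#' record, so integer sampling rates are required; both channels are truncated
#' to the common whole-second duration.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param eeg_range,emg_range Physical range (microvolts) declared for
#'   quantization, as `c(min, max)`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, eeg_range = c(-1000, 1000),
                      emg_range = c(-500, 500)) {
  stopifnot(inherits(rec, "recording"))
  if (rec$eeg_rate != round(rec$eeg_rate) || rec$emg_rate != round(rec$emg_rate)) {
    stop("EDF writing requires integer sampling rates")
  }
  n_rec <- floor(min(length(rec$eeg) / rec$eeg_rate,
                     length(rec$emg) / rec$emg_rate))
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")

  con <- file(path, "wb")
  on.exit(close(con))

  ns <- 2L
  header_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("somnotree", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_num(header_bytes, 8),
    edf_pad("", 44),
    edf_num(n_rec, 8),
    edf_num(1, 8),
    edf_num(ns, 4)
  ), con, eos = NULL)

  labels <- c("EEG", "EMG")
  phys_min <- c(eeg_range[1], emg_range[1])
  phys_max <- c(eeg_range[2], emg_range[2])
  spr <- c(rec$eeg_rate, rec$emg_rate)
  fields <- c(
    vapply(labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),                 # transducer
    rep(edf_pad("uV", 8), ns),                # physical dimension
    vapply(phys_min, edf_num, "", width = 8),
    vapply(phys_max, edf_num, "", width = 8),
    rep(edf_num(-32768, 8), ns),
    rep(edf_num(32767, 8), ns),
    rep(edf_pad("", 80), ns),                 # prefiltering
    vapply(spr, edf_num, "", width = 8),
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  quantize <- function(x, lo, hi) {
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  }
  eeg_d <- quantize(rec$eeg, eeg_range[1], eeg_range[2])
  emg_d <- quantize(rec$emg, emg_range[1], emg_range[2])
  for (r in seq_len(n_rec)) {
    writeBin(eeg_d[((r - 1) * spr[1] + 1):(r * spr[1])], con, size = 2,
             endian = "little")
    writeBin(emg_d[((r - 1) * spr[2] + 1):(r * spr[2])], con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a two-channel EDF file into a recording
#'
#' Channels are matched by regular expressions against the EDF signal labels;
#' sampling rates are taken from the file header (samples per record divided
#' by record duration) and never resampled.
#'
#' @param path EDF file path.
#' @param eeg_pattern,emg_pattern Case-insensitive regular expressions
#'   identifying the EEG and EMG channel labels.
#' @param epoch_s Epoch length used for the channel-duration tolerance.
#' @return A [recording()].
#' @export
read_edf <- function(path, eeg_pattern = "EEG", emg_pattern = "EMG",
                     epoch_s = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- rawToChar(readBin(con, "raw", 256))
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  subject <- field(hdr, 9, 80)
  n_rec <- as.integer(field(hdr, 237, 8))
  rec_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 2) {
    stop("ill-formed EDF file or fewer than 2 signals: ", path)
  }

  sig_hdr <- rawToChar(readBin(con, "raw", 256 * ns))
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, "")
  }
  off <- 0
  labels <- take(16, off); off <- off + 16 * ns
  off <- off + 80 * ns                       # transducer
  off <- off + 8 * ns                        # physical dimension
  phys_min <- as.numeric(take(8, off)); off <- off + 8 * ns
  phys_max <- as.numeric(take(8, off)); off <- off + 8 * ns
  dig_min <- as.numeric(take(8, off)); off <- off + 8 * ns
  dig_max <- as.numeric(take(8, off)); off <- off + 8 * ns
  off <- off + 80 * ns                       # prefiltering
  spr <- as.integer(take(8, off))

  pick <- function(pattern, what) {
    i <- grep(pattern, labels, ignore.case = TRUE)
    if (length(i) == 0) {
      stop(sprintf("channel not found: no label matches '%s' (available: %s)",
                   pattern, paste(labels, collapse = ", ")))
    }
    i[1]
  }
  i_eeg <- pick(eeg_pattern, "EEG")
  i_emg <- pick(emg_pattern, "EMG")

  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      data[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2,
                                signed = TRUE, endian = "little")
    }
  }
  to_phys <- function(i) {
    d <- unlist(data[[i]], use.names = FALSE)
    phys_min[i] + (d - dig_min[i]) / (dig_max[i] - dig_min[i]) *
      (phys_max[i] - phys_min[i])
  }
  recording(
    eeg = to_phys(i_eeg), eeg_rate = spr[i_eeg] / rec_dur,
    emg = to_phys(i_emg), emg_rate = spr[i_emg] / rec_dur,
    subject_id = subject, epoch_s = epoch_s
  )
}
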