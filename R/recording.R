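#' Construct a polysomnography recording
#'
#' A `recording` pairs one EEG channel and one EMG channel, each with its own
#' sampling rate, as acquired in rodent sleep studies (EEG nominally 200 Hz,
#' EMG nominally 500 Hz). The two channels are required to cover the same time
#' span to within one scoring epoch; the common analyzable duration is the
#' shorter of the two, truncated downstream to whole epochs.
#'
#' @param eeg Numeric vector of EEG samples (microvolts).
#' @param eeg_rate EEG sampling rate in Hz.
#' @param emg Numeric vector of EMG samples (microvolts).
#' @param emg_rate EMG sampling rate in Hz.
#' @param subject_id Optional subject identifier.
#' @param start_time_s Optional recording start time in seconds, used to align
#'   hypnogram summaries to the light-dark cycle (zeitgeber time).
#' @param epoch_s Epoch length in seconds used for the duration-mismatch
#'   tolerance (default 10).
#'
#' @return An object of class `recording`.
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 7 * seq(0, 10, by = 1/200)[-1]), 200,
#'                  rnorm(5000), 500)
#' rec
recording <- function(eeg, eeg_rate, emg, emg_rate, subject_id = "",
                      start_time_s = 0, epoch_s = 10) {
  eeg <- as.numeric(eeg)
  emg <- as.numeric(emg)
  if (!is.finite(eeg_rate) || eeg_rate <= 0 ||
      !is.finite(emg_rate) || emg_rate <= 0) {
    stop("sampling rates must be finite and positive")
  }
  if (anyNA(eeg) || anyNA(emg) || !all(is.finite(eeg)) || !all(is.finite(emg))) {
    stop("all samples must be finite")
  }
  dur_eeg <- length(eeg) / eeg_rate
  dur_emg <- length(emg) / emg_rate
  if (abs(dur_eeg - dur_emg) > epoch_s) {
    stop(sprintf(
      "channel duration mismatch: EEG %.2f s vs EMG %.2f s exceeds one %g-s epoch",
      dur_eeg, dur_emg, epoch_s
    ))
  }
  structure(
    list(
      eeg = eeg, eeg_rate = eeg_rate,
      emg = emg, emg_rate = emg_rate,
      subject_id = subject_id, start_time_s = start_time_s
    ),
    class = "recording"
  )
}

#' Common analyzable duration of a recording
#'
#' @param rec A [recording()].
#' @return Duration in seconds: the minimum of the two channel durations.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  min(length(rec$eeg) / rec$eeg_rate, length(rec$emg) / rec$emg_rate)
}

#' @export
print.recording <- function(x, ...) {
  cat("Polysomnography recording",
      if (nzchar(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  cat(sprintf("  EEG: %d samples @ %g Hz (%.1f s)\n",
              length(x$eeg), x$eeg_rate, length(x$eeg) / x$eeg_rate))
  cat(sprintf("  EMG: %d samples @ %g Hz (%.1f s)\n",
              length(x$emg), x$emg_rate, length(x$emg) / x$emg_rate))
  invisible(x)
}
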