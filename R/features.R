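#' Canonical EEG frequency bands
#'
#' Bands are half-open intervals `[lo, hi)` on the 0.5-Hz grid of a 2-s
#' periodogram: `lo` 0-0.5 Hz (the DC bin, tracking baseline shifts from
#' movement), `delta` 0.5-5, `theta` 6-9, `alpha` 10.5-15 (the rat spindle
#' band), `beta` 22-30, `gamma` 35-45, and `total` 0-30 Hz used as the
#' denominator of the power ratios. The gaps between bands (5-6, 9-10.5,
#' 15-22, 30-35 Hz) are excluded by design.
#'
#' @return Data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("lo", "delta", "theta", "alpha", "beta", "gamma", "total"),
    lo_hz = c(0, 0.5, 6, 10.5, 22, 35, 0),
    hi_hz = c(0.5, 5, 9, 15, 30, 45, 30)
  )
}

#' Names of the ten segment features
#' @return Character vector: six band powers (dB), three power ratios, and
#'   the rectified EMG energy.
#' @export
feature_names <- function() {
  c("sp_lo", "sp_delta", "sp_theta", "sp_alpha", "sp_beta", "sp_gamma",
    "pr_lo", "pr_delta", "pr_alpha", "emg_energy")
}

#' Partition a recording into epochs of 2-s segments
#'
#' Every 10-s scoring epoch is divided into five non-overlapping 2-s segments;
#' a trailing partial epoch is discarded.
#'
#' @param rec A [recording()].
#' @param epoch_s Epoch length in seconds (default 10).
#' @param segment_s Segment length in seconds (default 2); must divide
#'   `epoch_s`.
#' @return Data frame with one row per segment: `epoch`, `segment`, and the
#'   segment start/end times `t0`, `t1` in seconds.
#' @export
segment_epochs <- function(rec, epoch_s = 10, segment_s = 2) {
  stopifnot(inherits(rec, "recording"))
  if (epoch_s %% segment_s != 0) {
    stop("epoch_s must be an integer multiple of segment_s")
  }
  dur <- recording_duration(rec)
  n_epochs <- floor(dur / epoch_s)
  if (n_epochs < 1) {
    stop(sprintf("recording too short: %.2f s < one %g-s epoch", dur, epoch_s))
  }
  k <- epoch_s / segment_s
  epoch <- rep(seq_len(n_epochs), each = k)
  segment <- rep(seq_len(k), times = n_epochs)
  t0 <- (epoch - 1) * epoch_s + (segment - 1) * segment_s
  data.frame(epoch = epoch, segment = segment, t0 = t0, t1 = t0 + segment_s)
}

#' One-sided periodogram of a signal segment
#'
#' Rectangular window, no demeaning (the DC bin carries the baseline-shift
#' information the movement-artifact rules rely on). Bin powers are scaled so
#' that their sum equals the mean square of the segment (Parseval); DC and
#' Nyquist bins are not doubled. A 2-s segment yields a 0.5-Hz grid.
#'
#' @param x Numeric segment of samples.
#' @param rate Sampling rate in Hz.
#' @param segment_s Expected segment duration in seconds (contract check).
#' @return List with `freq` (Hz) and `power` (one-sided, microvolt^2).
#' @export
periodogram <- function(x, rate, segment_s = 2) {
  n <- length(x)
  if (n != round(rate * segment_s)) {
    stop(sprintf("segment length %d does not match %g s at %g Hz",
                 n, segment_s, rate))
  }
  X <- stats::fft(x)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / n^2
  scale <- rep(2, half + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[half + 1] <- 1
  list(freq = (0:half) / segment_s, power = p * scale)
}

#' Mean band power in decibels
#'
#' The mean of the periodogram bin powers over the half-open band `[lo, hi)`,
#' expressed in dB with a small floor inside the logarithm so silent segments
#' stay finite (a zero segment reports -120 dB in every band).
#'
#' @param pg A [periodogram()].
#' @param lo_hz,hi_hz Band edges in Hz, interpreted as `[lo, hi)`.
#' @param floor_power Power floor added inside the log (default 1e-12).
#' @return Band power in dB.
#' @export
band_power_db <- function(pg, lo_hz, hi_hz, floor_power = 1e-12) {
  idx <- which(pg$freq >= lo_hz & pg$freq < hi_hz)
  if (length(idx) == 0) {
    stop(sprintf("band [%g, %g) contains no bins on the frequency grid",
                 lo_hz, hi_hz))
  }
  10 * log10(mean(pg$power[idx]) + floor_power)
}

#' Band power ratio
#'
#' Sum of raw bin powers in a band divided by the sum over the total band
#' (0-30 Hz by default). Defined as 0 when the total power is 0.
#'
#' @inheritParams band_power_db
#' @param total_lo,total_hi Edges of the reference band.
#' @return Ratio in `[0, 1]`.
#' @export
power_ratio <- function(pg, lo_hz, hi_hz, total_lo = 0, total_hi = 30) {
  num <- sum(pg$power[pg$freq >= lo_hz & pg$freq < hi_hz])
  den <- sum(pg$power[pg$freq >= total_lo & pg$freq < total_hi])
  if (den == 0) return(0)
  num / den
}

#' Zero-phase band-pass filter for the EMG channel
#'
#' 4th-order Butterworth, 10-100 Hz, applied forward and backward
#' ([signal::filtfilt()]) over the whole channel before segmentation so no
#' phase shift disturbs the EEG/EMG time alignment.
#'
#' @param x EMG samples.
#' @param rate EMG sampling rate in Hz; must exceed 200 Hz so the 100-Hz edge
#'   is below Nyquist.
#' @param band Pass band in Hz.
#' @param order Filter order per pass.
#' @return Filtered series of the same length.
#' @export
emg_bandpass <- function(x, rate, band = c(10, 100), order = 4) {
  if (rate <= 2 * band[2]) {
    stop(sprintf("EMG rate %g Hz too low for a %g-Hz band edge", rate, band[2]))
  }
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Rectified EMG energy of a segment
#'
#' Mean absolute amplitude of the band-passed EMG over the segment.
#'
#' @param x Filtered EMG segment.
#' @return Non-negative scalar (microvolts).
#' @export
emg_energy <- function(x) {
  mean(abs(x))
}

#' Extract the ten per-segment features of a recording
#'
#' Segments the recording ([segment_epochs()]), computes six EEG band powers
#' (dB), three raw band power ratios, and the rectified EMG energy for every
#' 2-s segment. EEG and EMG features for segment k always cover the same
#' time window even though the channels are sampled at different rates; no
#' resampling is performed.
#'
#' @param rec A [recording()].
#' @param epoch_s,segment_s Epoch and segment lengths in seconds.
#' @return A `feature_matrix`: data frame with `epoch`, `segment`, and the
#'   ten columns of [feature_names()]; attributes carry the segmentation and
#'   rate metadata.
#' @export
extract_features <- function(rec, epoch_s = 10, segment_s = 2) {
  plan <- segment_epochs(rec, epoch_s, segment_s)
  bands <- band_definitions()
  band_row <- function(nm) bands[bands$name == nm, ]

  n_eeg <- rec$eeg_rate * segment_s
  n_emg <- rec$emg_rate * segment_s
  if (n_eeg != round(n_eeg) || n_emg != round(n_emg)) {
    stop("segment length must contain a whole number of samples on both channels")
  }
  emg_f <- emg_bandpass(rec$emg, rec$emg_rate)

  feats <- matrix(NA_real_, nrow = nrow(plan), ncol = 10,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(plan))) {
    i_eeg <- (plan$t0[i] * rec$eeg_rate + 1):(plan$t1[i] * rec$eeg_rate)
    i_emg <- (plan$t0[i] * rec$emg_rate + 1):(plan$t1[i] * rec$emg_rate)
    pg <- periodogram(rec$eeg[i_eeg], rec$eeg_rate, segment_s)
    sp <- vapply(c("lo", "delta", "theta", "alpha", "beta", "gamma"),
                 function(nm) {
                   b <- band_row(nm)
                   band_power_db(pg, b$lo_hz, b$hi_hz)
                 }, 0)
    pr <- vapply(c("lo", "delta", "alpha"),
                 function(nm) {
                   b <- band_row(nm)
                   power_ratio(pg, b$lo_hz, b$hi_hz)
                 }, 0)
    feats[i, ] <- c(sp, pr, emg_energy(emg_f[i_emg]))
  }
  out <- cbind(plan[c("epoch", "segment")], as.data.frame(feats))
  structure(out,
            eeg_rate = rec$eeg_rate, emg_rate = rec$emg_rate,
            epoch_s = epoch_s, segment_s = segment_s,
            class = c("feature_matrix", "data.frame"))
}
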