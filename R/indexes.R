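# Stage indexes derived from the normalized features. All symbols below are
# the decile-normalized features: EMG = emg_energy, lo = 0-0.5 Hz band power,
# delta/theta/alpha/beta/gamma the remaining band powers (dB scale before
# normalization). Denominators are floored because extreme-decile clipping
# maps roughly a tenth of all segments to exactly zero per feature; the floor
# is 1% of the normalized range, the scale below which a 2-s band-power
# estimate carries no usable information, so that floored denominators yield
# large-but-bounded index values instead of dominating every downstream
# average. Numerators are never floored.

.index_eps <- 0.01

#' Primary stage indexes of a segment
#'
#' Ratios of normalized features built to peak in one vigilance condition
#' each: `index_w = EMG * gamma / delta` (muscle tone and high-frequency EEG
#' against slow waves), `index_n = delta * alpha / gamma^2` (slow waves and
#' spindles against activation), `index_r = theta^3 / (delta * alpha * EMG)`
#' (pure theta with atonia), and the artifact index
#' `index_a = ((2 * lo) + beta) * gamma / (delta + theta + alpha + beta + gamma)`
#' (baseline shifts with broadband power increases).
#'
#' @param f A data frame (or list) of normalized features with the columns of
#'   [feature_names()]; vectorized over rows.
#' @param eps Denominator floor.
#' @return Data frame with columns `index_w`, `index_n`, `index_r`, `index_a`.
#' @export
#' @examples
#' primary_indexes(as.data.frame(as.list(setNames(rep(0.5, 10), feature_names()))))
primary_indexes <- function(f, eps = .index_eps) {
  flo <- function(x) pmax(x, eps)
  emg <- f$emg_energy
  sum_eeg <- f$sp_delta + f$sp_theta + f$sp_alpha + f$sp_beta + f$sp_gamma
  data.frame(
    index_w = emg * f$sp_gamma / flo(f$sp_delta),
    index_n = f$sp_delta * f$sp_alpha / flo(f$sp_gamma)^2,
    index_r = f$sp_theta^3 / (flo(f$sp_delta) * flo(f$sp_alpha) * flo(emg)),
    index_a = ((2 * f$sp_lo) + f$sp_beta) * f$sp_gamma / flo(sum_eeg)
  )
}

#' Secondary stage indexes of a segment
#'
#' Used by the second part of the decision tree: `index_1 = EMG * gamma /
#' delta` (identical to `index_w`), `index_2 = alpha * delta / theta`
#' (spindle/slow-wave content distinguishing NREM1 from wake),
#' `index_3 = theta * gamma / delta` and `index_4 = delta / theta`
#' (theta-vs-delta balance distinguishing transition sleep from NREM).
#'
#' @inheritParams primary_indexes
#' @return Data frame with columns `index_1` .. `index_4`.
#' @export
secondary_indexes <- function(f, eps = .index_eps) {
  flo <- function(x) pmax(x, eps)
  data.frame(
    index_1 = f$emg_energy * f$sp_gamma / flo(f$sp_delta),
    index_2 = f$sp_alpha * f$sp_delta / flo(f$sp_theta),
    index_3 = f$sp_theta * f$sp_gamma / flo(f$sp_delta),
    index_4 = f$sp_delta / flo(f$sp_theta)
  )
}

#' All eight segment indexes for a normalized feature matrix
#'
#' @param nfm Normalized feature matrix from [normalize_features()].
#' @param eps Denominator floor.
#' @return Data frame with `epoch`, `segment`, and the eight index columns.
#' @export
compute_indexes <- function(nfm, eps = .index_eps) {
  cbind(nfm[c("epoch", "segment")],
        primary_indexes(nfm, eps), secondary_indexes(nfm, eps))
}

#' Aggregate segment indexes to epoch level
#'
#' The four primary indexes of an epoch are the arithmetic means of the five
#' 2-s segment values; `snra = index_n + index_r + index_a` at epoch level is
#' the denominator of the artifact testing point.
#'
#' @param seg_idx Data frame of segment indexes for ONE epoch (exactly 5
#'   rows) with columns `index_w`, `index_n`, `index_r`, `index_a`.
#' @return One-row data frame: the four epoch-mean indexes plus `snra`.
#' @export
aggregate_epoch <- function(seg_idx) {
  if (nrow(seg_idx) != 5) {
    stop("an epoch aggregates exactly 5 segment index sets, got ", nrow(seg_idx))
  }
  out <- data.frame(
    index_w = mean(seg_idx$index_w),
    index_n = mean(seg_idx$index_n),
    index_r = mean(seg_idx$index_r),
    index_a = mean(seg_idx$index_a)
  )
  out$snra <- out$index_n + out$index_r + out$index_a
  out
}

#' Epoch-level index table for a whole recording
#'
#' @param seg_idx Segment index table from [compute_indexes()].
#' @return Data frame with one row per epoch: `epoch`, the four epoch-mean
#'   primary indexes, and `snra`.
#' @export
aggregate_epochs <- function(seg_idx) {
  epochs <- unique(seg_idx$epoch)
  out <- do.call(rbind, lapply(epochs, function(e) {
    aggregate_epoch(seg_idx[seg_idx$epoch == e, ])
  }))
  cbind(data.frame(epoch = epochs), out)
}

#' Epoch indexes from epoch-averaged features
#'
#' The first part of the decision tree works on one index value per epoch,
#' obtained from the average of the five 2-s normalized feature vectors:
#' features are averaged first, then the four primary indexes are computed
#' from the averaged features. Averaging before the ratio keeps the epoch
#' index stable when a single segment's clipped feature would otherwise blow
#' an index up through the denominator floor; the per-segment indexes of
#' [compute_indexes()] remain the currency of the second tree part, which
#' counts segments.
#'
#' @param nfm Normalized feature matrix from [normalize_features()].
#' @param eps Denominator floor.
#' @return Data frame with one row per epoch: `epoch`, `index_w`, `index_n`,
#'   `index_r`, `index_a`, and `snra = index_n + index_r + index_a`.
#' @export
epoch_indexes <- function(nfm, eps = .index_eps) {
  nm <- feature_names()
  ep <- stats::aggregate(nfm[nm], list(epoch = nfm$epoch), mean)
  idx <- primary_indexes(ep, eps)
  idx$snra <- idx$index_n + idx$index_r + idx$index_a
  cbind(ep["epoch"], idx)
}
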