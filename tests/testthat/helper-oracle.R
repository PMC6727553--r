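# Independent straight-line transcription of the seven testing points, kept
# free of any package code path so it can serve as a brute-force oracle for
# the tree implementation.
oracle_classify <- function(ep, segs, cfg = tree_config()) {
  # testing point 1: artifact
  snra <- ep$snra
  if (snra < 0.01) snra <- 0.01
  if (ep$index_a / snra > cfg$artifact_ratio_threshold) {
    return("W")
  }
  # part 1: condition by the largest epoch index, wake first on ties
  w <- ep$index_w; n <- ep$index_n; r <- ep$index_r
  if (w >= n && w >= r) {
    # testing point 2
    if (sum(segs$pr_lo > cfg$lowband_pr_threshold) >=
        cfg$lowband_wakeW_min_segments) return("W")
    # testing point 3
    if (sum(segs$index_1 > segs$index_2) == 5) return("W")
    return("N1")
  }
  if (n >= r) {
    # testing point 4
    if (sum(segs$pr_lo > cfg$lowband_pr_threshold) >=
        cfg$lowband_wakeN_min_segments) return("W")
    # testing point 5
    if (sum(segs$index_3 > segs$index_4) >= cfg$ts_min_segments) return("TS")
    # testing point 6
    if (sum(segs$pr_delta > cfg$delta_pr_threshold) >=
        cfg$nrem2_min_segments) return("N2")
    return("N1")
  }
  # testing point 7
  if (sum(segs$pr_alpha > cfg$alpha_pr_threshold) >= 1) return("TS")
  "R"
}

# Random epoch-level and segment-level inputs for the oracle comparison; a
# share of values is pinned exactly at the decision thresholds to exercise
# the strict-inequality boundaries.
random_epoch_inputs <- function() {
  pin <- function(v, at) {
    hit <- stats::runif(length(v)) < 0.15
    v[hit] <- sample(at, sum(hit), replace = TRUE)
    v
  }
  ep <- data.frame(
    index_w = stats::runif(1, 0, 3),
    index_n = stats::runif(1, 0, 3),
    index_r = stats::runif(1, 0, 3),
    index_a = stats::runif(1, 0, 3)
  )
  if (stats::runif(1) < 0.1) ep$index_n <- ep$index_w  # force ties sometimes
  ep$snra <- ep$index_n + ep$index_r + ep$index_a
  segs <- data.frame(
    pr_lo = pin(stats::runif(5), 0.5),
    pr_delta = pin(stats::runif(5), 0.5),
    pr_alpha = pin(stats::runif(5), 0.3),
    index_1 = stats::runif(5, 0, 2),
    index_2 = stats::runif(5, 0, 2),
    index_3 = stats::runif(5, 0, 2),
    index_4 = stats::runif(5, 0, 2)
  )
  eq <- stats::runif(5) < 0.15
  segs$index_2[eq] <- segs$index_1[eq]
  segs$index_4[eq] <- segs$index_3[eq]
  list(ep = ep, segs = segs)
}

# Small helper recordings used across test files.
sine_recording <- function(dur_s = 10, eeg_hz = 7, eeg_amp = 30,
                           emg_sd = 10, eeg_rate = 200, emg_rate = 500,
                           seed = 99) {
  set.seed(seed)
  t_e <- seq_len(dur_s * eeg_rate) / eeg_rate
  recording(
    eeg = eeg_amp * sin(2 * pi * eeg_hz * t_e),
    eeg_rate = eeg_rate,
    emg = rnorm(dur_s * emg_rate, sd = emg_sd),
    emg_rate = emg_rate
  )
}
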