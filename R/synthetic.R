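#' Default stage recipes for synthetic polysomnography
#'
#' Each vigilance stage is synthesized as Gaussian white broadband noise plus
#' stage-defining oscillatory components, mirroring the classical rat
#' signatures: wake has low-amplitude 7-Hz theta over a strong broadband
#' background and large EMG; NREM1 carries 2-Hz delta in under half the epoch
#' plus two 1-s sleep spindles (12 Hz) with reduced EMG; NREM2 carries
#' high-amplitude delta in more than half the epoch with low EMG; transition
#' sleep is theta intermixed with short high-amplitude spindles and low EMG;
#' REM is regular theta with essentially absent EMG. The EEG noise levels
#' encode the physiological ordering of high-frequency background activity
#' (wake > REM > NREM), which is what the gamma- and beta-band features pick
#' up.
#'
#' A recipe holds `tones` (data frame `freq_hz`, `amp_uv`, `segments` = how
#' many of the five 2-s segments per epoch carry the tone), an optional
#' `spindles` list (`freq_hz`, `amp_uv`, `burst_s`, `n_bursts`),
#' `eeg_noise_sd`, and `emg_noise_sd` (microvolts).
#'
#' @return Named list of recipes for stages `W`, `N1`, `N2`, `TS`, `R`.
#' @export
stage_recipes <- function() {
  list(
    W = list(
      tones = data.frame(freq_hz = 7, amp_uv = 5, segments = 5),
      spindles = NULL, eeg_noise_sd = 15, emg_noise_sd = 80
    ),
    N1 = list(
      tones = data.frame(freq_hz = 2, amp_uv = 60, segments = 2),
      spindles = list(freq_hz = 12, amp_uv = 40, burst_s = 1, n_bursts = 2),
      eeg_noise_sd = 5, emg_noise_sd = 25
    ),
    N2 = list(
      tones = data.frame(freq_hz = 2, amp_uv = 120, segments = 4),
      spindles = NULL, eeg_noise_sd = 4, emg_noise_sd = 15
    ),
    TS = list(
      tones = data.frame(freq_hz = 7, amp_uv = 40, segments = 5),
      spindles = list(freq_hz = 12, amp_uv = 60, burst_s = 1.5, n_bursts = 3),
      eeg_noise_sd = 5, emg_noise_sd = 10
    ),
    R = list(
      tones = data.frame(freq_hz = 7, amp_uv = 40, segments = 5),
      spindles = NULL, eeg_noise_sd = 8, emg_noise_sd = 3
    )
  )
}

#' Default per-epoch stage transition model
#'
#' A five-state Markov chain over `W, N1, N2, TS, R` favouring the
#' physiological progression (wake to light NREM to deep NREM, deep NREM
#' through transition sleep to REM, REM back to wake) with self-transition
#' probability 0.8, producing bout structure resembling real rodent
#' hypnograms without claiming distributional fidelity.
#'
#' @return List with the 5x5 row-stochastic `matrix` and the `initial`
#'   distribution.
#' @export
transition_model <- function() {
  lev <- stage_levels(5)
  m <- matrix(0, 5, 5, dimnames = list(lev, lev))
  m["W", c("W", "N1")] <- c(0.8, 0.2)
  m["N1", c("N1", "W", "N2")] <- c(0.8, 0.1, 0.1)
  m["N2", c("N2", "N1", "TS")] <- c(0.8, 0.1, 0.1)
  m["TS", c("TS", "R", "N2")] <- c(0.8, 0.15, 0.05)
  m["R", c("R", "W")] <- c(0.8, 0.2)
  init <- stats::setNames(c(1, 0, 0, 0, 0), lev)
  list(matrix = m, initial = init)
}

validate_transition_model <- function(model) {
  m <- model$matrix
  if (!is.matrix(m) || nrow(m) != 5 || ncol(m) != 5) {
    stop("transition matrix must be 5x5")
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (any(model$initial < 0) || abs(sum(model$initial) - 1) > 1e-12) {
    stop("initial distribution must be non-negative and sum to 1")
  }
  invisible(model)
}

#' Sample a ground-truth hypnogram from the transition model
#'
#' @param n_epochs Number of 10-s epochs.
#' @param model A [transition_model()].
#' @param seed Optional integer seed; the sample is deterministic given it.
#' @param epoch_s Epoch length in seconds.
#' @return A 5-stage [hypnogram()].
#' @export
generate_hypnogram <- function(n_epochs, model = transition_model(),
                               seed = NULL, epoch_s = 10) {
  stopifnot(n_epochs >= 1)
  validate_transition_model(model)
  if (!is.null(seed)) set.seed(seed)
  lev <- stage_levels(5)
  labels <- character(n_epochs)
  labels[1] <- sample(lev, 1, prob = model$initial)
  for (i in seq_len(n_epochs - 1)) {
    labels[i + 1] <- sample(lev, 1, prob = model$matrix[labels[i], ])
  }
  hypnogram(labels, epoch_s = epoch_s)
}

#' Synthesize one epoch of EEG and EMG for a stage
#'
#' Builds the EEG as broadband Gaussian noise plus the recipe's tonal
#' components (each occupying a random subset of the five 2-s segments when
#' its `segments` count is below 5) and spindle bursts placed at random
#' offsets inside distinct segments; the EMG is Gaussian noise at the
#' stage's tone level. Deterministic given a seed.
#'
#' @param stage Stage label (`W`, `N1`, `N2`, `TS`, `R`).
#' @param recipes Recipe library, see [stage_recipes()].
#' @param eeg_rate,emg_rate Sampling rates in Hz.
#' @param epoch_s,segment_s Epoch and segment lengths in seconds.
#' @param seed Optional seed.
#' @return List with `eeg` and `emg` sample vectors.
#' @export
synthesize_epoch <- function(stage, recipes = stage_recipes(),
                             eeg_rate = 200, emg_rate = 500,
                             epoch_s = 10, segment_s = 2, seed = NULL) {
  recipe <- recipes[[stage]]
  if (is.null(recipe)) stop("no recipe for stage '", stage, "'")
  if (!is.null(seed)) set.seed(seed)
  n_eeg <- round(eeg_rate * epoch_s)
  n_emg <- round(emg_rate * epoch_s)
  k <- epoch_s / segment_s
  t_eeg <- (seq_len(n_eeg) - 1) / eeg_rate
  seg_of <- floor(t_eeg / segment_s) + 1

  eeg <- stats::rnorm(n_eeg, sd = recipe$eeg_noise_sd)
  # Raised-cosine onset/offset ramps keep an oscillation's power inside its
  # own band: a hard-switched sinusoid splatters power across the spectrum.
  add_burst <- function(eeg, freq, amp, on, ramp_s = 0.25) {
    m <- sum(on)
    if (m == 0) return(eeg)
    phase <- stats::runif(1, 0, 2 * pi)
    env <- rep(1, m)
    nr <- min(round(ramp_s * eeg_rate), floor(m / 2))
    if (nr > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      env[seq_len(nr)] <- ramp
      env[seq.int(m - nr + 1, m)] <- rev(ramp)
    }
    eeg[on] <- eeg[on] + amp * env * sin(2 * pi * freq * t_eeg[on] + phase)
    eeg
  }
  tones <- recipe$tones
  if (!is.null(tones)) {
    for (j in seq_len(nrow(tones))) {
      if (tones$segments[j] >= k) {
        eeg <- add_burst(eeg, tones$freq_hz[j], tones$amp_uv[j],
                         rep(TRUE, n_eeg))
      } else {
        for (s in sample(seq_len(k), tones$segments[j])) {
          eeg <- add_burst(eeg, tones$freq_hz[j], tones$amp_uv[j],
                           seg_of == s)
        }
      }
    }
  }
  sp <- recipe$spindles
  if (!is.null(sp)) {
    for (s in sample(seq_len(k), sp$n_bursts)) {
      t0 <- (s - 1) * segment_s +
        stats::runif(1, 0, max(segment_s - sp$burst_s, 0))
      eeg <- add_burst(eeg, sp$freq_hz, sp$amp_uv,
                       t_eeg >= t0 & t_eeg < t0 + sp$burst_s)
    }
  }
  emg <- stats::rnorm(n_emg, sd = recipe$emg_noise_sd)
  list(eeg = eeg, emg = emg)
}

#' Generate a full synthetic recording for a ground-truth hypnogram
#'
#' Concatenates [synthesize_epoch()] output for every epoch of the
#' hypnogram. Bit-identical given the same seed.
#'
#' @param hyp Ground-truth 5-stage [hypnogram()].
#' @param recipes Recipe library.
#' @param eeg_rate,emg_rate Sampling rates in Hz.
#' @param seed Optional seed.
#' @param subject_id Identifier stored in the recording.
#' @return A [recording()] whose ground truth is `hyp`.
#' @export
generate_recording <- function(hyp, recipes = stage_recipes(),
                               eeg_rate = 200, emg_rate = 500,
                               seed = NULL, subject_id = "synthetic") {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nlevels(hyp) != 5) stop("ground truth must be a 5-stage hypnogram")
  missing <- setdiff(unique(as.character(hyp)), names(recipes))
  if (length(missing) > 0) {
    stop("no recipe for stage(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  epoch_s <- attr(hyp, "epoch_s")
  out <- lapply(as.character(hyp), function(st) {
    synthesize_epoch(st, recipes, eeg_rate, emg_rate, epoch_s = epoch_s)
  })
  recording(
    eeg = unlist(lapply(out, `[[`, "eeg"), use.names = FALSE),
    eeg_rate = eeg_rate,
    emg = unlist(lapply(out, `[[`, "emg"), use.names = FALSE),
    emg_rate = emg_rate,
    subject_id = subject_id, epoch_s = epoch_s
  )
}
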