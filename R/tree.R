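#' Decision-tree configuration
#'
#' All tunable constants of the two-part, seven-testing-point tree. The
#' defaults are the fixed values of the published rule set: artifact ratio
#' 0.9, band-power-ratio thresholds 0.5 (low band and delta) and 0.3 (alpha),
#' and the 1/2/3 segment-count cutoffs. All threshold comparisons are strict
#' (`>`); values exactly at a threshold fall to the else branch.
#'
#' @param artifact_ratio_threshold Testing point 1: epoch is an artifact when
#'   `index_a / snra` exceeds this.
#' @param lowband_pr_threshold Raw 0-0.5 Hz power-ratio threshold (testing
#'   points 2 and 4).
#' @param delta_pr_threshold Raw delta power-ratio threshold (testing point 6).
#' @param alpha_pr_threshold Raw alpha power-ratio threshold (testing point 7).
#' @param lowband_wakeW_min_segments Segments breaching the low-band ratio
#'   needed to call wake inside the W branch (testing point 2).
#' @param lowband_wakeN_min_segments Same inside the N branch (testing
#'   point 4).
#' @param ts_min_segments Segments with `index_3 > index_4` needed to call
#'   transition sleep (testing point 5).
#' @param nrem2_min_segments Segments breaching the delta ratio needed to call
#'   NREM2 (testing point 6).
#' @param tie_priority Order in which exact ties of the three primary epoch
#'   indexes are broken; wake first by default.
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(artifact_ratio_threshold = 0.9,
                        lowband_pr_threshold = 0.5,
                        delta_pr_threshold = 0.5,
                        alpha_pr_threshold = 0.3,
                        lowband_wakeW_min_segments = 1,
                        lowband_wakeN_min_segments = 2,
                        ts_min_segments = 3,
                        nrem2_min_segments = 3,
                        tie_priority = c("W", "N", "R")) {
  thr <- c(artifact_ratio_threshold, lowband_pr_threshold,
           delta_pr_threshold, alpha_pr_threshold)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)")
  counts <- c(lowband_wakeW_min_segments, lowband_wakeN_min_segments,
              ts_min_segments, nrem2_min_segments)
  if (any(counts < 1 | counts > 5)) stop("segment counts must lie in 1..5")
  if (!setequal(tie_priority, c("W", "N", "R"))) {
    stop("tie_priority must order W, N, R")
  }
  structure(
    list(artifact_ratio_threshold = artifact_ratio_threshold,
         lowband_pr_threshold = lowband_pr_threshold,
         delta_pr_threshold = delta_pr_threshold,
         alpha_pr_threshold = alpha_pr_threshold,
         lowband_wakeW_min_segments = lowband_wakeW_min_segments,
         lowband_wakeN_min_segments = lowband_wakeN_min_segments,
         ts_min_segments = ts_min_segments,
         nrem2_min_segments = nrem2_min_segments,
         tie_priority = tie_priority),
    class = "tree_config"
  )
}

#' Testing point 1: movement-artifact detection
#'
#' An epoch whose artifact index dominates the sleep indexes
#' (`index_a / (index_n + index_r + index_a) > 0.9`) is flagged as a
#' movement artifact; artifact epochs are scored as wake downstream but keep
#' their flag.
#'
#' @param epoch_idx One-row epoch index set from [aggregate_epoch()].
#' @param cfg A [tree_config()].
#' @return Logical.
#' @export
detect_artifact <- function(epoch_idx, cfg = tree_config()) {
  ratio <- epoch_idx$index_a / max(epoch_idx$snra, .index_eps)
  ratio > cfg$artifact_ratio_threshold
}

#' Part 1: assign the W / N / R condition of an epoch
#'
#' The condition is the arg-max of the three epoch-mean primary indexes;
#' exact ties are broken by the configured priority order (wake first).
#'
#' @inheritParams detect_artifact
#' @return `"W"`, `"N"`, or `"R"`.
#' @export
classify_condition <- function(epoch_idx, cfg = tree_config()) {
  v <- c(W = epoch_idx$index_w, N = epoch_idx$index_n, R = epoch_idx$index_r)
  v <- v[cfg$tie_priority]
  names(v)[which.max(v)]
}

#' Part 2 refinements of the three conditions
#'
#' Given the five 2-s segments of an epoch, apply the second-part testing
#' points of the tree. `segments` must hold the RAW band power ratios
#' (`pr_lo`, `pr_delta`, `pr_alpha`) and the secondary indexes (`index_1` ..
#' `index_4`) per segment.
#'
#' * W branch (testing points 2-3): wake if the low-band ratio breaches 0.5
#'   in at least 1 segment, else wake if `index_1 > index_2` in all five
#'   segments, else NREM1.
#' * N branch (testing points 4-6, in order): wake if the low-band ratio
#'   breaches 0.5 in at least 2 segments; else transition sleep if
#'   `index_3 > index_4` in at least 3 segments; else NREM2 if the delta
#'   ratio breaches 0.5 in at least 3 segments; else NREM1.
#' * R branch (testing point 7): transition sleep if the alpha ratio breaches
#'   0.3 in at least 1 segment, else REM.
#'
#' @param segments Data frame of the epoch's 5 segments.
#' @param cfg A [tree_config()].
#' @return Stage label.
#' @export
refine_stage_W <- function(segments, cfg = tree_config()) {
  stopifnot(nrow(segments) == 5)
  if (sum(segments$pr_lo > cfg$lowband_pr_threshold) >=
      cfg$lowband_wakeW_min_segments) {
    return("W")
  }
  if (all(segments$index_1 > segments$index_2)) return("W")
  "N1"
}

#' @rdname refine_stage_W
#' @export
refine_stage_N <- function(segments, cfg = tree_config()) {
  stopifnot(nrow(segments) == 5)
  if (sum(segments$pr_lo > cfg$lowband_pr_threshold) >=
      cfg$lowband_wakeN_min_segments) {
    return("W")
  }
  if (sum(segments$index_3 > segments$index_4) >= cfg$ts_min_segments) {
    return("TS")
  }
  if (sum(segments$pr_delta > cfg$delta_pr_threshold) >=
      cfg$nrem2_min_segments) {
    return("N2")
  }
  "N1"
}

#' @rdname refine_stage_W
#' @export
refine_stage_R <- function(segments, cfg = tree_config()) {
  stopifnot(nrow(segments) == 5)
  if (sum(segments$pr_alpha > cfg$alpha_pr_threshold) >= 1) return("TS")
  "R"
}

#' Classify a single epoch through the full tree
#'
#' Runs testing point 1 (artifact), the part-1 condition arg-max, and the
#' matching part-2 refinement, returning the decision together with an audit
#' trace.
#'
#' @param epoch_idx One-row epoch index set ([aggregate_epoch()]).
#' @param segments The epoch's 5 segment rows with raw `pr_*` ratios and
#'   secondary indexes.
#' @param cfg A [tree_config()].
#' @return List with `stage`, `condition`, `artifact`, and `testing_point`
#'   (the point that fixed the decision).
#' @export
classify_epoch <- function(epoch_idx, segments, cfg = tree_config()) {
  if (detect_artifact(epoch_idx, cfg)) {
    return(list(stage = "W", condition = "A", artifact = TRUE,
                testing_point = 1L))
  }
  cond <- classify_condition(epoch_idx, cfg)
  if (cond == "W") {
    stage <- refine_stage_W(segments, cfg)
    tp <- if (stage == "W") {
      if (sum(segments$pr_lo > cfg$lowband_pr_threshold) >=
          cfg$lowband_wakeW_min_segments) 2L else 3L
    } else 3L
  } else if (cond == "N") {
    stage <- refine_stage_N(segments, cfg)
    tp <- switch(stage, W = 4L, TS = 5L, N2 = 6L, N1 = 6L)
  } else {
    stage <- refine_stage_R(segments, cfg)
    tp <- 7L
  }
  list(stage = stage, condition = cond, artifact = FALSE, testing_point = tp)
}

#' Score a recording into a five-stage hypnogram
#'
#' The end-to-end pipeline: feature extraction on 2-s segments, per-recording
#' extreme-decile normalization, stage-index computation, and the two-part
#' decision tree on every 10-s epoch. Deterministic: the same recording
#' always yields the same hypnogram.
#'
#' @param rec A [recording()].
#' @param cfg A [tree_config()].
#' @param bounds Optional stored normalization bounds ([read_bounds()]); by
#'   default they are computed from this recording's own segments.
#' @param epoch_s,segment_s Epoch and segment lengths in seconds.
#' @return An object of class `sleep_score`: a list with the 5-stage
#'   `hypnogram` (artifact epochs labelled W and flagged), the per-epoch
#'   decision table `decisions` (stage, condition, artifact flag, deciding
#'   testing point), `features` (raw), `normalized` features, segment and
#'   epoch `indexes`, the normalization `bounds`, and the `config`.
#' @export
#' @examples
#' \donttest{
#' hyp <- generate_hypnogram(60, seed = 1)
#' rec <- generate_recording(hyp, seed = 2)
#' fit <- score_recording(rec)
#' summary(fit)
#' }
score_recording <- function(rec, cfg = tree_config(), bounds = NULL,
                            epoch_s = 10, segment_s = 2) {
  fm <- extract_features(rec, epoch_s, segment_s)
  nfm <- normalize_features(fm, bounds)
  seg_idx <- compute_indexes(nfm)
  ep_idx <- epoch_indexes(nfm)

  seg_audit <- cbind(seg_idx,
                     fm[c("pr_lo", "pr_delta", "pr_alpha")])
  epochs <- ep_idx$epoch
  n <- length(epochs)
  stage <- character(n)
  condition <- character(n)
  artifact <- logical(n)
  tp <- integer(n)
  for (i in seq_len(n)) {
    segs <- seg_audit[seg_audit$epoch == epochs[i], ]
    d <- classify_epoch(ep_idx[i, ], segs, cfg)
    stage[i] <- d$stage
    condition[i] <- d$condition
    artifact[i] <- d$artifact
    tp[i] <- d$testing_point
  }
  structure(
    list(
      hypnogram = hypnogram(stage, epoch_s = epoch_s, artifact = artifact),
      decisions = data.frame(epoch = epochs, stage = stage,
                             condition = condition, artifact = artifact,
                             testing_point = tp),
      features = fm,
      normalized = nfm,
      indexes = list(segment = seg_idx, epoch = ep_idx),
      bounds = attr(nfm, "bounds"),
      config = cfg,
      subject_id = rec$subject_id
    ),
    class = "sleep_score"
  )
}

#' @export
print.sleep_score <- function(x, ...) {
  cat("Rule-based sleep staging\n")
  if (nzchar(x$subject_id)) cat("Subject:", x$subject_id, "\n")
  cat(sprintf("%d epochs of %g s\n", length(x$hypnogram),
              attr(x$hypnogram, "epoch_s")))
  print(table(Stage = factor(as.character(x$hypnogram),
                             levels = stage_levels(5))))
  cat(sprintf("Artifact epochs: %d\n", sum(x$decisions$artifact)))
  invisible(x)
}

#' @export
summary.sleep_score <- function(object, ...) {
  tab <- table(factor(as.character(object$hypnogram),
                      levels = stage_levels(5)))
  epoch_s <- attr(object$hypnogram, "epoch_s")
  out <- data.frame(
    stage = names(tab),
    epochs = as.integer(tab),
    hours = as.numeric(tab) * epoch_s / 3600,
    percent = 100 * as.numeric(tab) / length(object$hypnogram)
  )
  structure(list(stages = out,
                 n_epochs = length(object$hypnogram),
                 n_artifact = sum(object$decisions$artifact),
                 conditions = table(object$decisions$condition)),
            class = "summary.sleep_score")
}

#' @export
print.summary.sleep_score <- function(x, ...) {
  cat(sprintf("Sleep staging summary (%d epochs, %d artifact)\n",
              x$n_epochs, x$n_artifact))
  print(x$stages, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a scored recording or hypnogram as a stage-time trace
#'
#' @param x A `sleep_score` or [hypnogram()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sleep_score <- function(x, ...) {
  plot(x$hypnogram, ...)
}

#' @export
plot.hypnogram <- function(x, ...) {
  epoch_s <- attr(x, "epoch_s")
  lev <- rev(levels(x))
  t_h <- (seq_along(x) - 1) * epoch_s / 3600
  y <- match(as.character(x), lev)
  graphics::plot(t_h, y, type = "s", yaxt = "n", xlab = "Time (h)",
                 ylab = "", main = "Hypnogram", ...)
  graphics::axis(2, at = seq_along(lev), labels = lev, las = 1)
  invisible(x)
}
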