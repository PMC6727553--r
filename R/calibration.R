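#' Extreme-decile bounds of a feature series
#'
#' The per-recording normalization anchors: the mean of the 10% smallest
#' values and the mean of the 10% largest values. The decile count is
#' `ceiling(0.1 * n)`, at least 1, so tiny series fall back to the plain
#' minimum and maximum.
#'
#' @param values Numeric vector of finite feature values.
#' @return List with `min_val` and `max_val`.
#' @export
#' @examples
#' extreme_decile_bounds(1:100) # min 5.5 (mean of 1..10), max 95.5
extreme_decile_bounds <- function(values) {
  n <- length(values)
  if (n == 0) stop("empty feature series")
  if (anyNA(values) || !all(is.finite(values))) {
    stop("feature series must be finite")
  }
  k <- max(1L, ceiling(0.1 * n))
  s <- sort(values)
  list(min_val = mean(s[seq_len(k)]), max_val = mean(s[seq.int(n - k + 1, n)]))
}

#' Normalize values to [0, 1] by extreme-decile bounds
#'
#' Values are mapped affinely so the decile bounds become 0 and 1, then
#' clipped into `[0, 1]`. Degenerate bounds (a constant feature) map every
#' value to 0.5 so downstream index denominators stay defined without biasing
#' toward any stage.
#'
#' @param values Numeric vector.
#' @param bounds Bounds from [extreme_decile_bounds()].
#' @return Numeric vector in `[0, 1]`.
#' @export
decile_normalize <- function(values, bounds = extreme_decile_bounds(values)) {
  rng <- bounds$max_val - bounds$min_val
  if (rng <= 0) return(rep(0.5, length(values)))
  pmin(pmax((values - bounds$min_val) / rng, 0), 1)
}

#' Distribution distance between a feature under two stages
#'
#' Separability score used to pick features for decision nodes: with stage
#' means `mA`, `mB` and standard deviations `sA`, `sB`,
#' `DD = 1 - (sA + sB) / (2 |mA - mB|)` when the spreads fit inside twice the
#' mean separation, and 0 otherwise (overlapping distributions). Identical
#' point distributions (equal means, zero spread) are defined as 0: no
#' separation.
#'
#' @param mean_a,sd_a,mean_b,sd_b Distribution statistics of the feature in
#'   the two stages; standard deviations must be non-negative.
#' @return DD in `[0, 1]`, symmetric in the two stages.
#' @export
#' @examples
#' distribution_distance(0.2, 0.1, 0.8, 0.1) # 1 - 0.2/1.2
distribution_distance <- function(mean_a, sd_a, mean_b, sd_b) {
  stopifnot(sd_a >= 0, sd_b >= 0)
  sep <- 2 * abs(mean_a - mean_b)
  spread <- sd_a + sd_b
  if (sep == 0) return(0)
  if (spread > sep) return(0)
  1 - spread / sep
}

#' Threshold between the extremes of a feature series
#'
#' Midpoint between the upper decile pulled down by half its spread and the
#' lower decile pushed up by half its spread:
#' `0.5 * [(mean(top 10%) - sd(top 10%)/2) + (mean(bottom 10%) + sd(bottom 10%)/2)]`.
#' Deciles follow the [extreme_decile_bounds()] counting rule; standard
#' deviations use the n-1 denominator, with a single-element decile
#' contributing zero spread.
#'
#' @param values Numeric vector.
#' @return Threshold in feature units.
#' @export
feature_threshold <- function(values) {
  n <- length(values)
  if (n == 0) stop("empty feature series")
  k <- max(1L, ceiling(0.1 * n))
  s <- sort(values)
  bot <- s[seq_len(k)]
  top <- s[seq.int(n - k + 1, n)]
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  0.5 * ((mean(top) - 0.5 * sd0(top)) + (mean(bot) + 0.5 * sd0(bot)))
}

#' Per-recording normalization bounds for every feature
#'
#' Computes [extreme_decile_bounds()] for each of the ten features over all
#' 2-s segments of a recording, eliminating between-subject amplitude
#' differences. Bounds can be exported with [write_bounds()] and reused.
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @return Data frame with columns `feature`, `min_val`, `max_val`.
#' @export
feature_bounds <- function(fm) {
  nm <- feature_names()
  out <- lapply(nm, function(f) {
    b <- extreme_decile_bounds(fm[[f]])
    data.frame(feature = f, min_val = b$min_val, max_val = b$max_val)
  })
  do.call(rbind, out)
}

#' Normalize a feature matrix
#'
#' Applies [decile_normalize()] per feature using per-recording bounds
#' (computed from the matrix itself unless stored bounds are supplied).
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @param bounds Optional bounds data frame from [feature_bounds()] or
#'   [read_bounds()].
#' @return A feature matrix of the same shape with all features in `[0, 1]`;
#'   the bounds used are attached as attribute `bounds`.
#' @export
normalize_features <- function(fm, bounds = NULL) {
  if (is.null(bounds)) bounds <- feature_bounds(fm)
  out <- fm
  for (f in feature_names()) {
    b <- bounds[bounds$feature == f, ]
    if (nrow(b) != 1) stop("bounds missing for feature ", f)
    out[[f]] <- decile_normalize(fm[[f]],
                                 list(min_val = b$min_val, max_val = b$max_val))
  }
  attr(out, "bounds") <- bounds
  out
}
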