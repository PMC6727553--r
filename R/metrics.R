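#' Expert-consensus epoch mask
#'
#' Epochs on which two independent scorers agree; only these enter the
#' validation statistics, removing ambiguous epochs from the reference.
#'
#' @param h1,h2 Two [hypnogram()]s of equal length on the same alphabet.
#' @return Logical vector, `TRUE` where the labels agree.
#' @export
consensus_epochs <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("hypnograms differ in length")
  if (!identical(levels(h1), levels(h2))) {
    stop("hypnograms use different stage alphabets")
  }
  as.character(h1) == as.character(h2)
}

#' Confusion matrix between a reference and a test staging
#'
#' @param reference,test [hypnogram()]s (or factors on a shared alphabet) of
#'   equal length. Rows of the result are reference labels, columns test
#'   labels.
#' @param mask Optional logical mask (e.g. from [consensus_epochs()])
#'   restricting which epochs are counted.
#' @return Square integer matrix with the stage labels as dimnames.
#' @export
confusion <- function(reference, test, mask = NULL) {
  if (length(reference) != length(test)) stop("stagings differ in length")
  if (!identical(levels(reference), levels(test))) {
    stop("stagings use different stage alphabets")
  }
  if (!is.null(mask)) {
    reference <- reference[mask]
    test <- test[mask]
  }
  lev <- levels(reference)
  m <- table(factor(as.character(reference), levels = lev),
             factor(as.character(test), levels = lev))
  matrix(as.integer(m), nrow = length(lev),
         dimnames = list(reference = lev, test = lev))
}

#' Overall agreement of a confusion matrix
#'
#' @param cm Square count matrix.
#' @return Percentage: `100 * trace / total`.
#' @export
overall_agreement <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts")
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(Pr(a) - Pr(e)) / (1 - Pr(e))` with observed
#' agreement `Pr(a) = trace/total` and chance agreement
#' `Pr(e) = sum_i row_i * col_i / total^2`. Degenerate single-category tables
#' (`Pr(e) = 1`) return `NA`.
#'
#' @param cm Square count matrix.
#' @return Kappa, or `NA` if undefined.
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts")
  pa <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) return(NA_real_)
  (pa - pe) / (1 - pe)
}

#' Per-stage sensitivity, specificity, and predictive values
#'
#' One-vs-rest statistics for every stage of a confusion matrix. The
#' `reference_axis` names the axis treated as the true condition:
#' `"rows"` is the conventional choice when rows hold the expert reference;
#' `"columns"` treats the column margin as the condition, which is the
#' convention used in the published validation tables this package ships as
#' fixtures. Statistics with a zero denominator are reported as `NA`.
#'
#' @param cm Square count matrix with dimnames.
#' @param reference_axis `"rows"` (default) or `"columns"`.
#' @return Data frame with one row per stage: `stage`, `se`, `sp`, `ppv`,
#'   `npv`, all percentages.
#' @export
stage_metrics <- function(cm, reference_axis = c("rows", "columns")) {
  reference_axis <- match.arg(reference_axis)
  if (reference_axis == "columns") cm <- t(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts")
  lev <- rownames(cm)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- lapply(seq_along(lev), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(stage = lev[i],
               se = pct(tp, tp + fn),
               sp = pct(tn, tn + fp),
               ppv = pct(tp, tp + fp),
               npv = pct(tn, tn + fn))
  })
  do.call(rbind, out)
}

#' Landis-Koch interpretation band of a kappa value
#'
#' Bands: poor (< 0), slight (0-0.20), fair (0.21-0.40), moderate
#' (0.41-0.60), substantial (0.61-0.80), excellent (> 0.80). Values falling
#' in the unprinted gaps between bands are assigned by their two-decimal
#' rounding.
#'
#' @param kappa Finite kappa value.
#' @return Character band label.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.finite(kappa))
  r <- round(kappa, 2)
  if (r < 0) "poor"
  else if (r <= 0.20) "slight"
  else if (r <= 0.40) "fair"
  else if (r <= 0.60) "moderate"
  else if (r <= 0.80) "substantial"
  else "excellent"
}

#' Mean and standard deviation of a per-subject statistic
#'
#' @param values Numeric vector, one value per subject.
#' @return List with `mean` and `sd` (n-1 denominator; `NA` when fewer than
#'   two subjects).
#' @export
subject_summary <- function(values) {
  list(mean = mean(values),
       sd = if (length(values) < 2) NA_real_ else stats::sd(values))
}

#' Hours per stage in the light and dark periods
#'
#' Splits a hypnogram at the light-dark boundary of a 12-12 (configurable)
#' cycle and tallies time in each stage per period. Epoch midpoints decide
#' period membership.
#'
#' @param hyp A [hypnogram()].
#' @param light_onset_s Clock time (seconds) of light onset.
#' @param light_duration_s Length of the light period in seconds (default
#'   12 h).
#' @param start_time_s Clock time at which the hypnogram starts.
#' @return Data frame: one row per stage, columns `light_h` and `dark_h`.
#' @export
summarize_hypnogram <- function(hyp, light_onset_s = 0,
                                light_duration_s = 12 * 3600,
                                start_time_s = 0) {
  epoch_s <- attr(hyp, "epoch_s")
  mid <- start_time_s + (seq_along(hyp) - 0.5) * epoch_s
  in_light <- ((mid - light_onset_s) %% 86400) < light_duration_s
  lev <- levels(hyp)
  tally <- function(keep) {
    as.numeric(table(factor(as.character(hyp)[keep], levels = lev))) *
      epoch_s / 3600
  }
  data.frame(stage = lev, light_h = tally(in_light), dark_h = tally(!in_light))
}

#' Agreement report in the layout of a validation table
#'
#' Convenience wrapper producing the confusion matrix together with the
#' per-stage statistics, overall agreement, kappa, and its Landis-Koch band.
#'
#' @param reference,test [hypnogram()]s on a shared alphabet.
#' @param mask Optional consensus mask.
#' @param reference_axis Passed to [stage_metrics()].
#' @return List with elements `confusion`, `stage_metrics`,
#'   `overall_agreement`, `kappa`, `kappa_band`.
#' @export
agreement_report <- function(reference, test, mask = NULL,
                             reference_axis = "rows") {
  cm <- confusion(reference, test, mask)
  list(
    confusion = cm,
    stage_metrics = stage_metrics(cm, reference_axis),
    overall_agreement = overall_agreement(cm),
    kappa = cohens_kappa(cm),
    kappa_band = kappa_band(cohens_kappa(cm))
  )
}
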