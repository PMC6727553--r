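# Published validation fixtures shipped with the package: the 5-stage and
# 3-stage expert-consensus vs automatic-staging confusion matrices from a
# 20-rat, 168,656-epoch validation study, and the per-subject agreement table.

#' Published validation fixtures
#'
#' `validation_confusion(5)` and `validation_confusion(3)` return the
#' 5-stage / 3-stage confusion matrices (rows: expert consensus; columns:
#' automatic staging) from the published 20-rat validation;
#' `validation_subjects()` returns the per-subject agreement and kappa table.
#' These serve as arithmetic fixtures for the agreement statistics, not as
#' outputs of this package's scorer.
#'
#' @param n_stages 5 or 3.
#' @return A count matrix with stage dimnames, or a data frame for
#'   `validation_subjects()`.
#' @export
validation_confusion <- function(n_stages = 5) {
  file <- switch(as.character(n_stages),
                 "5" = "confusion_5stage.csv",
                 "3" = "confusion_3stage.csv",
                 stop("n_stages must be 5 or 3"))
  path <- system.file("extdata", file, package = "somnotree", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  dimnames(m) <- list(reference = d$reference, test = colnames(d)[-1])
  storage.mode(m) <- "integer"
  m
}

#' @rdname validation_confusion
#' @export
validation_subjects <- function() {
  path <- system.file("extdata", "subject_agreement.csv",
                      package = "somnotree", mustWork = TRUE)
  utils::read.csv(path)
}
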