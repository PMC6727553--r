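#' Stage label alphabets
#'
#' Two alphabets are used: the 5-stage scheme `W, N1, N2, TS, R`
#' (wake, light NREM, deep NREM, transition sleep, REM) and the collapsed
#' 3-stage scheme `W, N, R`. A hypnogram always uses exactly one of them.
#'
#' @param n_stages 5 or 3.
#' @return Character vector of stage tokens.
#' @export
stage_levels <- function(n_stages = 5) {
  switch(as.character(n_stages),
    "5" = c("W", "N1", "N2", "TS", "R"),
    "3" = c("W", "N", "R"),
    stop("n_stages must be 5 or 3")
  )
}

#' Construct a hypnogram
#'
#' An ordered sequence of vigilance-stage labels at a fixed epoch length,
#' optionally carrying a per-epoch movement-artifact flag.
#'
#' @param labels Character vector or factor of stage labels.
#' @param epoch_s Epoch length in seconds (default 10).
#' @param artifact Optional logical vector, one flag per epoch.
#' @param n_stages Alphabet: 5 (default) or 3. Labels are validated against it.
#' @return An object of class `hypnogram`: a factor with attributes `epoch_s`
#'   and `artifact`.
#' @export
#' @examples
#' hypnogram(c("W", "N1", "N2", "TS", "R"))
hypnogram <- function(labels, epoch_s = 10, artifact = NULL, n_stages = 5) {
  lev <- stage_levels(n_stages)
  labels <- as.character(labels)
  bad <- which(!labels %in% lev)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage label '%s' at epoch %d (alphabet: %s)",
                 labels[bad[1]], bad[1], paste(lev, collapse = ", ")))
  }
  if (!is.null(artifact)) {
    artifact <- as.logical(artifact)
    if (length(artifact) != length(labels)) {
      stop("artifact flags must have one entry per epoch")
    }
  }
  structure(factor(labels, levels = lev),
            epoch_s = epoch_s, artifact = artifact,
            class = c("hypnogram", "factor"))
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("Hypnogram: %d epochs of %g s (%s-stage)\n",
              length(x), attr(x, "epoch_s"),
              if (nlevels(x) == 5) "5" else "3"))
  print(table(Stage = factor(as.character(x), levels = levels(x))))
  art <- attr(x, "artifact")
  if (!is.null(art)) cat(sprintf("Artifact epochs: %d\n", sum(art)))
  invisible(x)
}

#' Collapse a 5-stage hypnogram to the 3-stage scheme
#'
#' NREM1, NREM2, and transition sleep merge into a single NREM stage; wake and
#' REM map to themselves. Epoch length and artifact flags are preserved.
#'
#' @param hyp A 5-stage [hypnogram()].
#' @return A 3-stage [hypnogram()] of the same length.
#' @export
#' @examples
#' collapse_to_3stage(hypnogram(c("W", "N1", "N2", "TS", "R")))
collapse_to_3stage <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nlevels(hyp) != 5) stop("collapse_to_3stage expects a 5-stage hypnogram")
  map <- c(W = "W", N1 = "N", N2 = "N", TS = "N", R = "R")
  hypnogram(unname(map[as.character(hyp)]),
            epoch_s = attr(hyp, "epoch_s"),
            artifact = attr(hyp, "artifact"),
            n_stages = 3)
}

#' Read / write hypnograms as delimited text
#'
#' The on-disk format is CSV with columns `epoch_index,stage,artifact` (the
#' artifact column is optional and 0/1 coded). Unknown stage tokens raise a
#' parse error citing the offending line.
#'
#' @param path File path.
#' @param n_stages Alphabet the labels are validated against (5 or 3).
#' @param epoch_s Epoch length in seconds.
#' @return `read_hypnogram` returns a [hypnogram()]; `write_hypnogram` returns
#'   its input invisibly.
#' @export
read_hypnogram <- function(path, n_stages = 5, epoch_s = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(d))) {
    stop("hypnogram file must have columns epoch_index,stage[,artifact]")
  }
  lev <- stage_levels(n_stages)
  bad <- which(!d$stage %in% lev)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage token '%s' at line %d of %s",
                 d$stage[bad[1]], bad[1] + 1L, path))
  }
  art <- if ("artifact" %in% names(d)) d$artifact == 1 else NULL
  hypnogram(d$stage, epoch_s = epoch_s, artifact = art, n_stages = n_stages)
}

#' @param hyp A [hypnogram()].
#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  d <- data.frame(epoch_index = seq_along(hyp),
                  stage = as.character(hyp))
  art <- attr(hyp, "artifact")
  if (!is.null(art)) d$artifact <- as.integer(art)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(hyp)
}
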