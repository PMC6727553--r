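#' Read and write recordings in EDF or delimited-text format
#'
#' The CSV dialect stores one column per channel (`eeg,emg` header), the
#' shorter channel padded with empty cells, with sampling rates and metadata
#' in a sidecar key-value config (`<path>.cfg` by default, keys `eeg_rate`,
#' `emg_rate`, optional `subject_id`). CSV roundtrips are exact decimal text;
#' EDF roundtrips are exact to the 16-bit quantization step of the declared
#' physical range.
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`; default inferred from the file extension.
#' @param config Sidecar config path for the CSV variant.
#' @param epoch_s Epoch length in seconds, for the channel-duration tolerance.
#' @param ... Passed on to [read_edf()] / [write_edf()] (channel label
#'   patterns, physical ranges).
#' @return `read_recording` returns a [recording()]; `write_recording` returns
#'   `path` invisibly.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           config = paste0(path, ".cfg"), epoch_s = 10, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    return(read_edf(path, epoch_s = epoch_s, ...))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- read_config(config)
  for (key in c("eeg_rate", "emg_rate")) {
    if (is.null(cfg[[key]])) {
      stop("sidecar config ", config, " must declare ", key)
    }
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  for (ch in c("eeg", "emg")) {
    if (!ch %in% names(d)) {
      stop(sprintf("channel not found: '%s' (available: %s)",
                   ch, paste(names(d), collapse = ", ")))
    }
  }
  grab <- function(ch) {
    v <- d[[ch]]
    as.numeric(v[!is.na(v) & v != ""])
  }
  recording(
    eeg = grab("eeg"), eeg_rate = as.numeric(cfg$eeg_rate),
    emg = grab("emg"), emg_rate = as.numeric(cfg$emg_rate),
    subject_id = if (is.null(cfg$subject_id)) "" else cfg$subject_id,
    epoch_s = epoch_s
  )
}

#' @param rec A [recording()].
#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv"),
                            config = paste0(path, ".cfg"), ...) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    return(invisible(write_edf(rec, path, ...)))
  }
  n <- max(length(rec$eeg), length(rec$emg))
  pad <- function(x) c(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                       rep("", n - length(x)))
  d <- data.frame(eeg = pad(rec$eeg), emg = pad(rec$emg))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  writeLines(c(
    paste0("eeg_rate=", format(rec$eeg_rate, digits = 17)),
    paste0("emg_rate=", format(rec$emg_rate, digits = 17)),
    paste0("subject_id=", rec$subject_id)
  ), config)
  invisible(path)
}

#' Read a key-value configuration file
#'
#' One `key=value` pair per line; blank lines and lines starting with `#` are
#' ignored. Values are returned as character strings.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2) out[[trimws(p[1])]] <- trimws(p[2])
  }
  out
}

#' Export / import per-recording normalization bounds
#'
#' Writing the extreme-decile bounds used to normalize a recording's features
#' lets the same recording be re-scored reproducibly, or a stored calibration
#' be applied to streaming data.
#'
#' @param bounds Data frame with columns `feature,min_val,max_val`, as
#'   produced by [feature_bounds()].
#' @param path CSV file path.
#' @return `read_bounds` returns the bounds data frame.
#' @export
write_bounds <- function(bounds, path) {
  stopifnot(all(c("feature", "min_val", "max_val") %in% names(bounds)))
  utils::write.csv(bounds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bounds
#' @export
read_bounds <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("feature", "min_val", "max_val") %in% names(d))) {
    stop("bounds file must have columns feature,min_val,max_val")
  }
  d
}
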