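#' Construct an RR-interval series
#'
#' An `rr_series` holds a subject's ordered inter-beat (RR) intervals in
#' milliseconds together with provenance metadata. RR intervals are the
#' durations between consecutive R peaks of the EKG's QRS complexes; their
#' beat-to-beat variation is the raw material of heart rate variability
#' analysis.
#'
#' @param intervals Numeric vector of RR intervals in milliseconds. All
#'   values must be strictly positive; the acquisition order is preserved.
#' @param subject_id Character scalar identifying the subject.
#' @param group_label Optional character scalar naming the subject's group.
#' @param source One of `"rr_file"`, `"ekg_derived"`, `"synthetic"`.
#' @return An object of class `rr_series`.
#' @examples
#' rr <- rr_series(c(850, 950, 1020), subject_id = "s01")
#' length(rr$intervals)
#' @export
rr_series <- function(intervals, subject_id = "unknown", group_label = NULL,
                      source = c("rr_file", "ekg_derived", "synthetic")) {
  source <- match.arg(source)
  intervals <- as.numeric(intervals)
  if (anyNA(intervals)) {
    stop("RR intervals must not contain missing values", call. = FALSE)
  }
  if (length(intervals) && any(intervals <= 0)) {
    stop("RR intervals must be strictly positive (milliseconds)",
         call. = FALSE)
  }
  if (length(intervals) && any(intervals < 10)) {
    # values this small almost always mean seconds were supplied; units are
    # fixed to ms and never guessed, so shout instead of converting
    warning("RR values below 10 ms found; intervals must be in milliseconds,",
            " not seconds", call. = FALSE)
  }
  structure(
    list(intervals = intervals,
         subject_id = as.character(subject_id)[1],
         group_label = if (is.null(group_label)) NULL
                       else as.character(group_label)[1],
         source = source),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("RR series: %d intervals (subject %s, source %s)\n",
              n, x$subject_id, x$source))
  if (!is.null(x$group_label)) cat("  group:", x$group_label, "\n")
  if (n) {
    cat(sprintf("  mean %.1f ms, range [%.1f, %.1f] ms\n",
                mean(x$intervals), min(x$intervals), max(x$intervals)))
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

as_rr_series <- function(x, ...) {
  if (inherits(x, "rr_series")) x else rr_series(x, ...)
}

#' Construct a raw EKG signal
#'
#' A thin container for a single-channel EKG trace: ordered amplitude
#' samples (arbitrary units) plus the sampling rate.
#'
#' @param samples Numeric vector of amplitude samples in acquisition order.
#' @param sampling_rate_hz Sampling rate in Hz; must be positive.
#' @return An object of class `ekg_signal`.
#' @export
ekg_signal <- function(samples, sampling_rate_hz) {
  sampling_rate_hz <- as.numeric(sampling_rate_hz)[1]
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("EKG samples must be numeric", call. = FALSE)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz),
            class = "ekg_signal")
}

#' @export
print.ekg_signal <- function(x, ...) {
  cat(sprintf("EKG signal: %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

# Shared line-oriented numeric reader. Blank lines and lines starting with
# "#" are skipped; commas and stray whitespace are tolerated as incidental
# delimiters but each surviving line must reduce to exactly one number.
parse_numeric_lines <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- numeric(length(idx))
  for (k in seq_along(idx)) {
    tok <- trimws(gsub(",", " ", lines[idx[k]], fixed = TRUE))
    tok <- strsplit(tok, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (length(num) != 1 || anyNA(num)) {
      stop(sprintf("cannot parse %s value at line %d of %s: \"%s\"",
                   what, idx[k], path, lines[idx[k]]), call. = FALSE)
    }
    vals[k] <- num
  }
  vals
}

#' Read a plain-text RR/IBI file
#'
#' Reads one RR interval per line, in milliseconds, preserving line order.
#' Blank lines and lines starting with `#` are ignored; a comma or extra
#' whitespace around the value is tolerated. This is the dialect used by
#' deposited inter-beat-interval (IBI) `.txt` files.
#'
#' @param path Path to the file.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param group_label Optional group label.
#' @return An [rr_series]. An empty file yields an empty series with a
#'   warning; a non-numeric line raises an error naming the line; a
#'   non-positive value raises a validation error.
#' @export
read_rr_file <- function(path, subject_id = NULL, group_label = NULL) {
  vals <- parse_numeric_lines(path, "RR")
  if (!length(vals)) {
    warning(sprintf("RR file %s contains no intervals", path), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  rr_series(vals, subject_id = subject_id, group_label = group_label,
            source = "rr_file")
}

#' Write an RR series to a plain-text file
#'
#' One interval (ms) per line, the same dialect [read_rr_file] reads.
#'
#' @param rr An [rr_series] or numeric vector of intervals in ms.
#' @param path Output path.
#' @param digits Number of significant digits to print (default 15, enough
#'   to round-trip doubles at printed precision).
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(rr, path, digits = 15) {
  rr <- as_rr_series(rr)
  writeLines(trimws(formatC(rr$intervals, digits = digits, format = "g")),
             path)
  invisible(path)
}

#' Read a plain-text single-channel EKG file
#'
#' One amplitude sample per line. The sampling rate is not stored in such
#' files and must be supplied by the caller.
#'
#' @param path Path to the file.
#' @param sampling_rate_hz Sampling rate in Hz (e.g. 100 for 100 Hz
#'   portable recorders).
#' @return An [ekg_signal].
#' @export
read_ekg_file <- function(path, sampling_rate_hz) {
  ekg_signal(parse_numeric_lines(path, "EKG"), sampling_rate_hz)
}
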