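#' Validate an onset sequence
#'
#' An onset sequence is the model's only input: event times in milliseconds,
#' finite, non-negative and strictly increasing. Durations are not part of
#' the representation — only when events begin.
#'
#' @param times numeric vector of event times in ms.
#' @param min_length minimum number of events required (tracking needs at
#'   least two so one hypothesis can be formed).
#' @param what label used in error messages.
#' @return The validated times, invisibly, as a plain double vector.
#' @examples
#' validate_onsets(c(0, 500, 1000))
#' @export
validate_onsets <- function(times, min_length = 2L, what = "onset") {
  if (!is.numeric(times))
    stop(what, " times must be numeric", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < min_length)
    stop("need at least ", min_length, " ", what, "s, got ", length(times),
         call. = FALSE)
  bad <- which(!is.finite(times) | times < 0)
  if (length(bad))
    stop(what, " time at position ", bad[1L],
         " is not a finite non-negative number", call. = FALSE)
  dec <- which(diff(times) <= 0)
  if (length(dec))
    stop(what, " times must be strictly increasing; violation at position ",
         dec[1L] + 1L, " (", format(times[dec[1L] + 1L]), " follows ",
         format(times[dec[1L]]), ")", call. = FALSE)
  invisible(times)
}

#' Read an onset (or tap, or beat) file
#'
#' Plain-text format: one event time per line; blank lines and lines starting
#' with `#` are ignored. Times are milliseconds by default; `units = "s"`
#' reads seconds and converts (all internal computation is in ms).
#'
#' @param path file to read.
#' @param units `"ms"` (default) or `"s"`.
#' @param min_length minimum number of events required (default 2).
#' @return Numeric vector of times in ms, strictly increasing.
#' @seealso [write_times()]
#' @export
read_onsets <- function(path, units = c("ms", "s"), min_length = 2L) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad))
    stop("cannot parse '", lines[bad[1L]], "' as a number (", path,
         " line ", lineno[bad[1L]], ")", call. = FALSE)
  if (units == "s") vals <- vals * 1000
  validate_onsets(vals, min_length = min_length)
  vals
}

#' Write event times to a plain-text file
#'
#' One time per line. Milliseconds are written with full precision (up to 15
#' significant digits, so a read/write round trip is value-preserving);
#' seconds are written with 3 decimals, the usual precision of beat
#' annotation files.
#'
#' @param times numeric vector of times in ms, strictly increasing.
#' @param path output file.
#' @param units output units, `"ms"` (default) or `"s"`.
#' @param header optional character vector written first as `#` comments.
#' @return `path`, invisibly.
#' @seealso [read_onsets()]
#' @export
write_times <- function(times, path, units = c("ms", "s"), header = NULL) {
  units <- match.arg(units)
  times <- validate_onsets(times, min_length = 1L, what = "event")
  out <- if (units == "s") sprintf("%.3f", times / 1000)
         else sprintf("%.15g", times)
  if (!is.null(header)) out <- c(paste0("# ", header), out)
  writeLines(out, path)
  invisible(path)
}
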