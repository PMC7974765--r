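# Glucose traces: construction, parsing, buffer-download merging, slicing.

#' Construct a glucose trace
#'
#' A glucose trace is one subject's time-ordered interstitial glucose record
#' on a nominal sampling grid (default one sample every 15 minutes), stored as
#' a tibble with columns `timestamp` (POSIXct, UTC), `glucose` (mg/dL) and
#' `source` (`"cgm_scan"` or `"fingerstick"`). The subject identifier, nominal
#' sampling interval, local time zone (used for all calendar-day metrics) and
#' any known data gaps travel as attributes.
#'
#' Invariants enforced: strictly increasing timestamps (no duplicates) and
#' glucose strictly inside the physiological reporting bounds (0, 500) mg/dL.
#'
#' @param samples data frame with columns `timestamp`, `glucose`, `source`
#'   (source defaults to `"cgm_scan"` when absent).
#' @param subject_id opaque subject identifier.
#' @param nominal_interval nominal sampling interval in minutes.
#' @param tz Olson time zone used to assign samples to local calendar days.
#' @param gaps optional tibble of known missing stretches (`start`, `end`).
#' @return A `glucose_trace` object.
#' @export
glucose_trace <- function(samples, subject_id = "S1", nominal_interval = 15,
                          tz = "UTC", gaps = NULL) {
  samples <- as_tibble(samples)
  if (!all(c("timestamp", "glucose") %in% names(samples))) {
    stop("samples must have columns `timestamp` and `glucose`", call. = FALSE)
  }
  if (!"source" %in% names(samples)) samples$source <- "cgm_scan"
  if (!inherits(samples$timestamp, "POSIXct")) {
    samples$timestamp <- as.POSIXct(samples$timestamp, tz = "UTC")
  }
  samples <- samples[order(samples$timestamp), c("timestamp", "glucose", "source")]
  validate_trace_samples(samples)
  if (is.null(gaps)) {
    gaps <- tibble(start = samples$timestamp[0], end = samples$timestamp[0])
  }
  structure(samples,
            class = c("glucose_trace", class(tibble())),
            subject_id = as.character(subject_id),
            nominal_interval = as.numeric(nominal_interval),
            tz = tz, gaps = as_tibble(gaps))
}

validate_trace_samples <- function(samples) {
  if (anyNA(samples$timestamp)) {
    stop("trace contains unparseable timestamps", call. = FALSE)
  }
  bad <- !is.finite(samples$glucose) |
    samples$glucose <= .gt_glucose_min | samples$glucose >= .gt_glucose_max
  if (any(bad)) {
    stop(sprintf("glucose outside plausible bounds (%g, %g) mg/dL at row %d",
                 .gt_glucose_min, .gt_glucose_max, which(bad)[1]),
         call. = FALSE)
  }
  if (anyDuplicated(samples$timestamp)) {
    stop("duplicate timestamps in trace", call. = FALSE)
  }
  if (!all(samples$source %in% .gt_sources)) {
    stop("source must be one of: ", paste(.gt_sources, collapse = ", "),
         call. = FALSE)
  }
  invisible(samples)
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> subject %s: %d samples, nominal %g min\n",
              attr(x, "subject_id"), nrow(x), attr(x, "nominal_interval")))
  if (nrow(x) > 0) {
    cat(sprintf("  span %s .. %s\n", format(x$timestamp[1]),
                format(x$timestamp[nrow(x)])))
  }
  ng <- nrow(attr(x, "gaps"))
  if (ng > 0) cat(sprintf("  %d known gap interval(s)\n", ng))
  invisible(x)
}

#' @export
subject_id <- function(trace) attr(trace, "subject_id")

#' Known missing stretches of a merged trace
#' @param trace a `glucose_trace`.
#' @return Tibble with columns `start`, `end`.
#' @export
trace_gaps <- function(trace) attr(trace, "gaps")

# keep attributes through dplyr/row subsetting
#' @export
`[.glucose_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("timestamp", "glucose", "source") %in% names(out))) {
    attributes(out)[c("subject_id", "nominal_interval", "tz", "gaps")] <-
      attributes(x)[c("subject_id", "nominal_interval", "tz", "gaps")]
    class(out) <- class(x)
  }
  out
}

#' Read a glucose trace from the canonical CSV table
#'
#' Expects a UTF-8 CSV with header
#' `subject_id,timestamp,glucose_mgdl,source`, ISO-8601 timestamps. Rows
#' belonging to other subjects are ignored; rows out of order are sorted.
#' Duplicate timestamps with equal glucose collapse silently (overlapping
#' buffer downloads legitimately repeat data); conflicting values are an
#' integrity error, as are glucose values outside (0, 500) mg/dL.
#'
#' @param path CSV file path.
#' @param subject_id subject whose rows to keep.
#' @inheritParams glucose_trace
#' @return A [glucose_trace()].
#' @export
parse_trace_table <- function(path, subject_id, nominal_interval = 15,
                              tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "glucose_mgdl", "source")
  if (!all(need %in% names(raw))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[raw$subject_id == subject_id, , drop = FALSE]
  ts <- parse_iso8601(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("malformed timestamp %s at data row %d of %s",
                 dQuote(raw$timestamp[bad]), bad, basename(path)),
         call. = FALSE)
  }
  samples <- tibble(timestamp = ts,
                    glucose = as.numeric(raw$glucose_mgdl),
                    source = raw$source)
  samples <- dedupe_samples(samples)
  glucose_trace(samples, subject_id = subject_id,
                nominal_interval = nominal_interval, tz = tz)
}

parse_iso8601 <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S%z")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%S")
  }
  still <- is.na(out)
  if (any(still)) {
    out[still] <- as.POSIXct(x[still], tz = "UTC",
                             format = "%Y-%m-%d %H:%M:%S")
  }
  out
}

# collapse exact duplicates; conflicting glucose at one timestamp is corrupt
dedupe_samples <- function(samples) {
  samples <- dplyr::distinct(samples)
  dup <- duplicated(samples$timestamp)
  if (any(dup)) {
    t_bad <- samples$timestamp[dup][1]
    stop(sprintf("conflicting glucose values at timestamp %s", format(t_bad)),
         call. = FALSE)
  }
  samples[order(samples$timestamp), , drop = FALSE]
}

#' Construct one flash-sensor download
#'
#' A scan download is the block of samples held in the device's memory at the
#' moment of a scan: at most `buffer_hours` (default 8 h) of samples ending at
#' `scan_time`. Samples older than the buffer at scan time were never
#' transferred and are unrecoverable.
#'
#' @param scan_time POSIXct scan instant.
#' @param samples data frame of samples (`timestamp`, `glucose`, optional
#'   `source`).
#' @param buffer_hours on-device memory depth in hours.
#' @return A `scan_download` object.
#' @export
scan_download <- function(scan_time, samples, buffer_hours = 8) {
  samples <- as_tibble(samples)
  if (!"source" %in% names(samples)) samples$source <- "cgm_scan"
  if (!inherits(samples$timestamp, "POSIXct")) {
    samples$timestamp <- as.POSIXct(samples$timestamp, tz = "UTC")
  }
  age <- as.numeric(difftime(scan_time, samples$timestamp, units = "hours"))
  if (any(age < 0 | age >= buffer_hours + 1e-9)) {
    stop("download samples must lie within (scan_time - buffer, scan_time]",
         call. = FALSE)
  }
  structure(list(scan_time = scan_time,
                 samples = samples[order(samples$timestamp), ],
                 buffer_hours = buffer_hours),
            class = "scan_download")
}

#' Merge overlapping buffer downloads into one trace
#'
#' Scans taken less than `buffer_hours` apart produce overlapping sample
#' blocks; the union deduplicated by timestamp reconstructs the continuous
#' trace. When consecutive scans are further apart than the buffer, the
#' oldest part of the inter-scan stretch was overwritten in device memory:
#' those stretches stay absent from the trace and are reported as gap
#' intervals (retrievable with [trace_gaps()]).
#'
#' Identical timestamps with equal glucose collapse to one sample; the same
#' timestamp with different values across downloads is an integrity error.
#'
#' @param downloads list of [scan_download()] objects from one subject.
#' @inheritParams glucose_trace
#' @return A [glucose_trace()] with a gap report attached.
#' @export
merge_scan_downloads <- function(downloads, subject_id = "S1",
                                 nominal_interval = 15, tz = "UTC") {
  stopifnot(length(downloads) >= 1)
  if (inherits(downloads, "scan_download")) downloads <- list(downloads)
  samples <- dedupe_samples(bind_rows(lapply(downloads, `[[`, "samples")))
  scan_times <- sort(do.call(c, lapply(downloads, `[[`, "scan_time")))
  buffer_h <- downloads[[1]]$buffer_hours
  gap_start <- gap_end <- scan_times[0]
  if (length(scan_times) > 1) {
    dt <- as.numeric(difftime(scan_times[-1], scan_times[-length(scan_times)],
                              units = "hours"))
    over <- which(dt > buffer_h)
    # the stretch (prev_scan, next_scan - buffer] was never downloaded
    gap_start <- scan_times[over]
    gap_end <- scan_times[over + 1] - buffer_h * 3600
  }
  glucose_trace(samples, subject_id = subject_id,
                nominal_interval = nominal_interval, tz = tz,
                gaps = tibble(start = gap_start, end = gap_end))
}

#' Extract the samples inside a closed time window
#'
#' Keeps samples with `start <= timestamp <= end` (closed on both ends, so a
#' 2-hour window on the 15-minute grid contains 9 samples). The empty slice is
#' allowed.
#'
#' @param trace a [glucose_trace()].
#' @param start,end window bounds (POSIXct), `start < end`.
#' @return A `glucose_trace` restricted to the window.
#' @export
slice_window <- function(trace, start, end) {
  stopifnot(start < end)
  keep <- trace$timestamp >= start & trace$timestamp <= end
  trace[keep, ]
}

#' Time span of a trace
#' @param trace a [glucose_trace()].
#' @return POSIXct vector `c(first, last)` (NULL for an empty trace).
#' @export
trace_span <- function(trace) {
  if (nrow(trace) == 0) return(NULL)
  c(trace$timestamp[1], trace$timestamp[nrow(trace)])
}

# local calendar day of each sample, per the trace's declared time zone
trace_local_days <- function(trace) {
  as.Date(trace$timestamp, tz = attr(trace, "tz") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
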