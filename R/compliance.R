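# Compliance analytics: scan-gap behavior against the 8-hour device buffer,
# pre-MTT fasting check, annotation rates.

#' Inter-scan gap statistics
#'
#' The flash sensor stores only the most recent `buffer_hours` of samples,
#' so consecutive scans further apart than the buffer lose data. This
#' reports the inter-scan intervals, how many exceeded the buffer, the total
#' unsampled duration `sum(max(0, interval - buffer))`, weekly medians of
#' the interval (weeks counted from the first scan) and the sign of the
#' change between the first and last week (scan fatigue shows as +1).
#'
#' @param scans POSIXct scan times (sorted internally if needed).
#' @param buffer_hours device memory depth, hours.
#' @return An object of class `scan_gap_report`: `intervals` (hours),
#'   `n_over_limit`, `data_lost` (hours), `median_by_week`, `trend`.
#' @export
scan_gap_stats <- function(scans, buffer_hours = 8) {
  stopifnot(length(scans) >= 1)
  scans <- sort(scans)
  if (length(scans) == 1) {
    return(structure(list(intervals = numeric(0), n_over_limit = 0L,
                          data_lost = 0, median_by_week = numeric(0),
                          trend = 0L, buffer_hours = buffer_hours),
                     class = "scan_gap_report"))
  }
  iv <- as.numeric(difftime(scans[-1], scans[-length(scans)], units = "hours"))
  week <- floor(as.numeric(difftime(scans[-length(scans)], scans[1],
                                    units = "days")) / 7)
  med <- vapply(split(iv, week), median, numeric(1))
  trend <- if (length(med) < 2) 0L else as.integer(sign(med[length(med)] - med[1]))
  structure(list(intervals = iv, n_over_limit = sum(iv > buffer_hours),
                 data_lost = sum(pmax(0, iv - buffer_hours)),
                 median_by_week = med, trend = trend,
                 buffer_hours = buffer_hours),
            class = "scan_gap_report")
}

#' @export
print.scan_gap_report <- function(x, ...) {
  cat(sprintf("<scan_gap_report> %d intervals, %d over the %g-h buffer, %.2f h lost\n",
              length(x$intervals), x$n_over_limit, x$buffer_hours,
              x$data_lost))
  invisible(x)
}

#' Pre-MTT fasting check
#'
#' A valid fasted meal-tolerance test requires a quiet glucose curve over
#' the fasting window before intake. The check looks at the
#' `fasting_hours` window ending at `t0`: with under 75% of the expected
#' grid points present the verdict is `insufficient_data`; with a
#' max-minus-min excursion above `excursion_limit`, or any detected peak
#' overlapping the window, it is `flagged`; otherwise `pass`. The verdict
#' depends only on glucose differences, so it is invariant to a constant
#' shift of the trace.
#'
#' @param trace a [glucose_trace()].
#' @param t0 MTT intake time.
#' @param fasting_hours required fasting duration (default 6 h).
#' @param excursion_limit largest max-minus-min excursion, mg/dL, still
#'   considered flat.
#' @param peaks optional [detect_peaks()] result; peaks overlapping the
#'   window force `flagged`.
#' @return An object of class `fasting_check`: `window_start`,
#'   `window_end`, `max_excursion`, `n_samples`, `verdict`.
#' @export
fasting_precheck <- function(trace, t0, fasting_hours = 6,
                             excursion_limit = 25, peaks = NULL) {
  w_start <- t0 - fasting_hours * 3600
  win <- trace[trace$timestamp >= w_start & trace$timestamp <= t0, ]
  step <- attr(trace, "nominal_interval")
  expected <- fasting_hours * 60 / step + 1
  excursion <- if (nrow(win) > 0) max(win$glucose) - min(win$glucose) else NA_real_
  verdict <- if (nrow(win) < 0.75 * expected) {
    "insufficient_data"
  } else {
    peak_overlap <- !is.null(peaks) && nrow(peaks) > 0 &&
      any(peaks$end >= w_start & peaks$start <= t0)
    if (excursion > excursion_limit || peak_overlap) "flagged" else "pass"
  }
  structure(list(window_start = w_start, window_end = t0,
                 max_excursion = excursion, n_samples = nrow(win),
                 verdict = verdict),
            class = "fasting_check")
}

#' @export
print.fasting_check <- function(x, ...) {
  cat(sprintf("<fasting_check> [%s .. %s]: %s (excursion %.1f mg/dL, %d samples)\n",
              format(x$window_start), format(x$window_end), x$verdict,
              x$max_excursion, x$n_samples))
  invisible(x)
}

#' Annotation-rate statistics
#'
#' Daily app-log counts over a study span: mean logs per day (days with no
#' logs count as zero), the variance-to-mean ratio of the daily counts, the
#' per-day counts themselves, and the sign of the change in weekly mean
#' between the first and last week.
#'
#' @param events an [annotation_events()] tibble (one subject).
#' @param span_days length of the observation span in whole days.
#' @param start first day of the span (Date; default the day of the first
#'   event).
#' @param tz time zone for local calendar days.
#' @return List: `mean_per_day`, `var_mean_ratio`, `per_day` (tibble `day`,
#'   `n`), `weekly_trend`.
#' @export
annotation_rate_stats <- function(events, span_days, start = NULL,
                                  tz = "UTC") {
  stopifnot(span_days >= 1)
  if (nrow(events) == 0) {
    days <- if (is.null(start)) Sys.Date() + seq_len(span_days) - 1
            else start + seq_len(span_days) - 1
    return(list(mean_per_day = 0, var_mean_ratio = 0,
                per_day = tibble(day = days, n = 0L), weekly_trend = 0L))
  }
  ev_day <- as.Date(events$timestamp, tz = tz)
  if (is.null(start)) start <- min(ev_day)
  days <- start + seq_len(span_days) - 1
  n <- vapply(days, function(d) sum(ev_day == d), integer(1))
  m <- mean(n)
  ratio <- if (m > 0) var(n) / m else 0
  week <- floor((seq_len(span_days) - 1) / 7)
  wm <- vapply(split(n, week), mean, numeric(1))
  trend <- if (length(wm) < 2) 0L else as.integer(sign(wm[length(wm)] - wm[1]))
  list(mean_per_day = m, var_mean_ratio = ratio,
       per_day = tibble(day = days, n = n), weekly_trend = trend)
}
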