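# Annotation events (smartphone log) and the cross-over study design.

#' Construct an annotation-event table
#'
#' App log entries: meal photos, exercise, alcohol, self-reported start of a
#' meal-tolerance test (`mtt_start`), and fingerstick glucose checks. Stored
#' as a tibble with columns `subject_id`, `timestamp`, `kind`, `payload`,
#' `value`; `value` (mg/dL) must be present exactly for fingerstick entries.
#'
#' @param events data frame with the columns above (`payload`/`value`
#'   optional).
#' @return A validated tibble of events sorted by subject then time.
#' @export
annotation_events <- function(events) {
  events <- as_tibble(events)
  if (!"payload" %in% names(events)) events$payload <- ""
  if (!"value" %in% names(events)) events$value <- NA_real_
  need <- c("subject_id", "timestamp", "kind", "payload", "value")
  stopifnot(all(need %in% names(events)))
  if (!inherits(events$timestamp, "POSIXct")) {
    events$timestamp <- parse_iso8601(as.character(events$timestamp))
  }
  events$value <- as.numeric(events$value)
  events$payload <- as.character(events$payload)
  if (!all(events$kind %in% .gt_event_kinds)) {
    stop("event kind must be one of: ", paste(.gt_event_kinds, collapse = ", "),
         call. = FALSE)
  }
  is_fs <- events$kind == "fingerstick"
  if (any(is_fs & is.na(events$value)) || any(!is_fs & !is.na(events$value))) {
    stop("`value` must be present exactly for fingerstick events",
         call. = FALSE)
  }
  events[order(events$subject_id, events$timestamp), need]
}

#' Read annotation events from CSV or JSON
#'
#' CSV files need the header `subject_id,timestamp,kind,payload,value`; JSON
#' files hold an array of objects with the same keys. Timestamps are ISO-8601.
#'
#' @param path file path (`.csv` or `.json`).
#' @return An [annotation_events()] tibble.
#' @export
parse_events <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE)
  }
  annotation_events(raw)
}

#' Construct a subject's cross-over design
#'
#' Two treatment periods (arms `product` and `placebo`, in randomized order)
#' separated by a washout. Periods must be chronological and non-overlapping;
#' period and washout durations are checked against configurable bounds
#' (defaults 13-17 days and 3-6 days).
#'
#' @param subject_id subject identifier.
#' @param periods data frame with columns `arm`, `start`, `end`.
#' @param washouts data frame with columns `start`, `end`.
#' @param period_bounds,washout_bounds allowed duration ranges in days.
#' @return A `study_design` object.
#' @export
study_design <- function(subject_id, periods, washouts,
                         period_bounds = c(13, 17), washout_bounds = c(3, 6)) {
  periods <- as_tibble(periods)
  washouts <- as_tibble(washouts)
  for (col in c("start", "end")) {
    if (!inherits(periods[[col]], "POSIXct")) {
      periods[[col]] <- parse_iso8601(as.character(periods[[col]]))
    }
    if (nrow(washouts) > 0 && !inherits(washouts[[col]], "POSIXct")) {
      washouts[[col]] <- parse_iso8601(as.character(washouts[[col]]))
    }
  }
  stopifnot(all(periods$arm %in% .gt_arms))
  if (is.unsorted(periods$start) ||
      any(periods$end[-nrow(periods)] > periods$start[-1])) {
    stop("periods must be chronological and non-overlapping", call. = FALSE)
  }
  dur <- as.numeric(difftime(periods$end, periods$start, units = "days"))
  if (any(dur < period_bounds[1] - 1e-9 | dur > period_bounds[2] + 1e-9)) {
    stop(sprintf("period duration outside [%g, %g] days for subject %s",
                 period_bounds[1], period_bounds[2], subject_id),
         call. = FALSE)
  }
  if (nrow(washouts) > 0) {
    wd <- as.numeric(difftime(washouts$end, washouts$start, units = "days"))
    if (any(wd < washout_bounds[1] - 1e-9 | wd > washout_bounds[2] + 1e-9)) {
      stop(sprintf("washout duration outside [%g, %g] days for subject %s",
                   washout_bounds[1], washout_bounds[2], subject_id),
           call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), periods = periods,
                 washouts = washouts),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> subject %s: %s\n", x$subject_id,
              paste(x$periods$arm, collapse = " -> ")))
  invisible(x)
}

#' Read cross-over designs from JSON
#'
#' The file holds one object, or an array of objects, of the form
#' `{subject_id, periods: [{arm, start, end}], washouts: [{start, end}]}`.
#'
#' @param path JSON file path.
#' @inheritParams study_design
#' @return A named list of [study_design()] objects keyed by subject.
#' @export
read_study_designs <- function(path, period_bounds = c(13, 17),
                               washout_bounds = c(3, 6)) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$subject_id)) raw <- list(raw)
  designs <- lapply(raw, function(d) {
    study_design(d$subject_id,
                 periods = bind_rows(lapply(d$periods, as_tibble)),
                 washouts = if (length(d$washouts))
                   bind_rows(lapply(d$washouts, as_tibble))
                 else tibble(start = character(), end = character()),
                 period_bounds = period_bounds,
                 washout_bounds = washout_bounds)
  })
  names(designs) <- vapply(designs, `[[`, "", "subject_id")
  designs
}
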