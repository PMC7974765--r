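# Consensus glycemic metrics: time in range, hypoglycemic episodes,
# postprandial tolerance, subject-level summary.

#' Glycemic metric thresholds
#'
#' Consensus values: hypoglycemia below 70 mg/dL sustained for at least two
#' consecutive samples (30 minutes on the 15-minute grid), target range
#' 70-180 mg/dL inclusive, and 2-hour postprandial glucose of 140 mg/dL or
#' above indicating impaired glucose tolerance.
#'
#' @param hypo_mgdl hypoglycemia threshold (strictly below).
#' @param range_low_mgdl,range_high_mgdl inclusive target range bounds.
#' @param postprandial_mgdl 2-h postprandial intolerance threshold (at or
#'   above).
#' @param hypo_min_consecutive minimum consecutive samples below threshold.
#' @return A list of class `metric_thresholds`.
#' @export
metric_thresholds <- function(hypo_mgdl = 70, range_low_mgdl = 70,
                              range_high_mgdl = 180, postprandial_mgdl = 140,
                              hypo_min_consecutive = 2) {
  stopifnot(range_low_mgdl < range_high_mgdl, hypo_mgdl > 0,
            hypo_min_consecutive >= 1)
  structure(list(hypo_mgdl = hypo_mgdl, range_low_mgdl = range_low_mgdl,
                 range_high_mgdl = range_high_mgdl,
                 postprandial_mgdl = postprandial_mgdl,
                 hypo_min_consecutive = hypo_min_consecutive),
            class = "metric_thresholds")
}

#' Fraction of sampled time in the target range
#'
#' Sample-weighted: each sample stands for one nominal interval of wear
#' time. Boundaries are inclusive (a sample at exactly 70 or 180 mg/dL is
#' in range).
#'
#' @param trace a non-empty [glucose_trace()].
#' @param thresholds [metric_thresholds()].
#' @return Fraction in `[0, 1]`.
#' @export
time_in_range <- function(trace, thresholds = metric_thresholds()) {
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  mean(trace$glucose >= thresholds$range_low_mgdl &
         trace$glucose <= thresholds$range_high_mgdl)
}

#' Hypoglycemic episodes
#'
#' Maximal runs of consecutive samples strictly below the hypoglycemia
#' threshold, kept when at least `hypo_min_consecutive` samples long
#' (>= 30 min of nominal time on the default grid). Consecutive means
#' contiguous on the sampling grid: runs separated by a data gap (spacing
#' beyond twice the nominal interval) are never joined.
#'
#' @inheritParams time_in_range
#' @return Tibble with columns `start`, `end`, `nadir`, `n_samples`,
#'   `duration_min` (nominal time represented, `n_samples` x interval).
#' @export
hypoglycemic_episodes <- function(trace, thresholds = metric_thresholds()) {
  step <- attr(trace, "nominal_interval")
  empty <- tibble(start = trace$timestamp[0], end = trace$timestamp[0],
                  nadir = numeric(0), n_samples = integer(0),
                  duration_min = numeric(0))
  if (nrow(trace) == 0) return(empty)
  low <- trace$glucose < thresholds$hypo_mgdl
  if (!any(low)) return(empty)
  gap_s <- 2 * step * 60
  contiguous <- c(TRUE, diff(as.numeric(trace$timestamp)) <= gap_s)
  # run id increments when lowness starts anew or continuity breaks
  run_break <- c(TRUE, diff(low) != 0) | !contiguous
  run <- cumsum(run_break)
  eps <- lapply(split(which(low), run[low]), function(idx) {
    if (length(idx) < thresholds$hypo_min_consecutive) return(NULL)
    tibble(start = trace$timestamp[idx[1]],
           end = trace$timestamp[idx[length(idx)]],
           nadir = min(trace$glucose[idx]),
           n_samples = length(idx),
           duration_min = length(idx) * step)
  })
  out <- bind_rows(eps)
  if (nrow(out) == 0) empty else out[order(out$start), ]
}

#' Two-hour postprandial intolerance flag
#'
#' Reads the glucose 120 minutes after a meal (nearest sample within 15
#' minutes; if none, linear interpolation between the bracketing samples)
#' and flags impaired tolerance when the value is at or above the
#' postprandial threshold.
#'
#' @param trace a [glucose_trace()].
#' @param meal_time meal intake time (POSIXct).
#' @param thresholds [metric_thresholds()].
#' @return List: `flag` (logical), `glucose` (value used), `at` (time of
#'   the value), `method` (`"nearest"` or `"interpolated"`).
#' @export
postprandial_intolerance_flag <- function(trace, meal_time,
                                          thresholds = metric_thresholds()) {
  target <- meal_time + 120 * 60
  dt <- abs(as.numeric(difftime(trace$timestamp, target, units = "mins")))
  i <- which.min(dt)
  if (length(i) == 1 && dt[i] <= 15) {
    value <- trace$glucose[i]
    at <- trace$timestamp[i]
    method <- "nearest"
  } else {
    before <- trace$timestamp < target
    after <- trace$timestamp > target
    if (!any(before) || !any(after)) {
      stop("no sample within 15 min of the 2-h postprandial point and no bracketing pair",
           call. = FALSE)
    }
    value <- approx(as.numeric(trace$timestamp), trace$glucose,
                    xout = as.numeric(target))$y
    at <- target
    method <- "interpolated"
  }
  list(flag = value >= thresholds$postprandial_mgdl, glucose = value,
       at = at, method = method)
}

#' Subject-level glycemic summary
#'
#' Mean glucose, SD, coefficient of variation, the three band percentages
#' (below / in / above the target range, partitioning sampled time), and
#' the hypoglycemic-episode count.
#'
#' @inheritParams time_in_range
#' @return List of named scalars (`pct_*` on the 0-100 scale).
#' @export
subject_summary <- function(trace, thresholds = metric_thresholds()) {
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  g <- trace$glucose
  below <- mean(g < thresholds$range_low_mgdl)
  above <- mean(g > thresholds$range_high_mgdl)
  in_range <- 1 - below - above
  m <- mean(g)
  list(mean_glucose = m, sd_glucose = sd(g),
       cv = if (length(g) > 1) sd(g) / m else 0,
       pct_below = 100 * below, pct_in_range = 100 * in_range,
       pct_above = 100 * above,
       n_hypo_episodes = nrow(hypoglycemic_episodes(trace, thresholds)))
}
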