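# Spike-function peak detection for glucose traces.
#
# Scoring follows the simplest member of the Palshikar family of spike
# functions: a point's score is the mean of the largest left-sided and
# largest right-sided increments within a k-sample neighborhood. Meal
# excursions score high; isolated sensor noise does not survive the
# score threshold plus prominence filter.

#' Peak-detection parameters
#'
#' @param k neighborhood half-width in samples (default 4 = 1 h each side on
#'   the 15-min grid).
#' @param h score threshold in SD units: a point is a spike candidate when
#'   its score exceeds `mean + h * sd` of the positive scores.
#' @param merge_window candidate points closer than this many minutes merge
#'   into one peak.
#' @param min_prominence minimum apex height above the local baseline,
#'   mg/dL.
#' @param smoothing centered moving-average width in samples applied before
#'   scoring (1 = none).
#' @param baseline_window half-width in samples of the window used to find
#'   the local baseline (minimum smoothed glucose) around an apex.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(k = 4, h = 1.0, merge_window = 60,
                        min_prominence = 20, smoothing = 3,
                        baseline_window = 8) {
  stopifnot(k >= 1, h > 0, merge_window >= 0, smoothing >= 1)
  structure(list(k = k, h = h, merge_window = merge_window,
                 min_prominence = min_prominence, smoothing = smoothing,
                 baseline_window = baseline_window),
            class = "peak_params")
}

#' Spike scores of a glucose series
#'
#' `score(i) = 1/2 * (max_j (x_i - x_(i-j)) + max_j (x_i - x_(i+j)))` over
#' `j = 1..k`; boundary points use only the available one-sided
#' neighborhood. Scores depend only on differences, so they are invariant to
#' adding a constant to the whole series.
#'
#' @param series numeric vector of glucose values on a regular grid.
#' @param k neighborhood half-width in samples.
#' @return Numeric vector of per-point scores.
#' @export
spike_score <- function(series, k = 4) {
  n <- length(series)
  if (n <= 2 * k) {
    stop(sprintf("series length %d too short for k = %d (need > 2k)", n, k),
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    lj <- i - seq_len(min(k, i - 1))
    rj <- i + seq_len(min(k, n - i))
    left <- if (length(lj)) max(series[i] - series[lj]) else NA_real_
    right <- if (length(rj)) max(series[i] - series[rj]) else NA_real_
    mean(c(left, right), na.rm = TRUE)
  }, numeric(1))
}

# centered moving average with shrinking edge windows
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Detect glucose peaks in a trace
#'
#' Pipeline: smooth with a short moving average, compute spike scores, keep
#' points scoring above `mean + h*sd` of the positive scores, merge kept
#' points closer than `merge_window` minutes into candidate peaks
#' (apex = maximum glucose in the cluster), estimate each peak's extent by
#' walking outward from the apex until glucose returns within 10% of the
#' prominence above the local baseline (or a data gap or renewed rise is
#' hit), and drop candidates with prominence below `min_prominence`.
#' Returned peaks are time-ordered and pairwise disjoint; peaks never span a
#' sampling gap.
#'
#' @param trace a [glucose_trace()] spanning more than `2k` samples.
#' @param params [peak_params()].
#' @return Tibble with columns `start`, `apex`, `end` (POSIXct),
#'   `apex_glucose`, `local_baseline`, `prominence` (mg/dL) and `score`.
#' @export
detect_peaks <- function(trace, params = peak_params()) {
  n <- nrow(trace)
  if (n <= 2 * params$k) {
    stop("trace too short for peak detection", call. = FALSE)
  }
  empty <- tibble(start = trace$timestamp[0], apex = trace$timestamp[0],
                  end = trace$timestamp[0], apex_glucose = numeric(0),
                  local_baseline = numeric(0), prominence = numeric(0),
                  score = numeric(0))
  sm <- moving_average(trace$glucose, params$smoothing)
  scores <- spike_score(sm, params$k)
  pos <- scores[scores > 0]
  if (length(pos) < 2) return(empty)
  thr <- mean(pos) + params$h * sd(pos)
  keep <- which(scores > thr)
  if (length(keep) == 0) return(empty)
  # treat spacing beyond twice the nominal grid as a gap peaks cannot span
  gap_s <- 2 * attr(trace, "nominal_interval") * 60
  ts_num <- as.numeric(trace$timestamp)
  # cluster candidate indices by time proximity
  cl_break <- c(TRUE, diff(ts_num[keep]) > params$merge_window * 60)
  cluster <- cumsum(cl_break)
  peaks <- lapply(split(keep, cluster), function(idx) {
    apex <- idx[which.max(trace$glucose[idx])]
    w <- max(1, apex - params$baseline_window):min(n, apex + params$baseline_window)
    # local baseline never looks across a gap
    w <- w[contiguous_with(ts_num, w, apex, gap_s)]
    local_baseline <- min(sm[w])
    prominence <- trace$glucose[apex] - local_baseline
    if (prominence < params$min_prominence) return(NULL)
    return_level <- local_baseline + 0.1 * prominence
    left <- walk_extent(sm, ts_num, apex, -1L, return_level, gap_s)
    right <- walk_extent(sm, ts_num, apex, +1L, return_level, gap_s)
    tibble(start = trace$timestamp[left], apex = trace$timestamp[apex],
           end = trace$timestamp[right],
           apex_glucose = trace$glucose[apex],
           local_baseline = local_baseline, prominence = prominence,
           score = scores[apex])
  })
  out <- bind_rows(peaks)
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$apex), ]
  enforce_disjoint(out, trace)
}

# indices of w contiguous with apex (no inter-sample gap exceeding gap_s)
contiguous_with <- function(ts_num, w, apex, gap_s) {
  ok <- rep(TRUE, length(w))
  ai <- match(apex, w)
  if (ai > 1) {
    for (i in (ai - 1):1) {
      if (!ok[i + 1] || ts_num[w[i + 1]] - ts_num[w[i]] > gap_s) ok[1:i] <- FALSE
    }
  }
  if (ai < length(w)) {
    for (i in (ai + 1):length(w)) {
      if (!ok[i - 1] || ts_num[w[i]] - ts_num[w[i - 1]] > gap_s) ok[i:length(w)] <- FALSE
    }
  }
  ok
}

# walk outward from the apex while the (smoothed) curve is above the return
# level, stopping at a data gap or when the curve starts rising again
walk_extent <- function(sm, ts_num, apex, dir, return_level, gap_s) {
  i <- apex
  n <- length(sm)
  repeat {
    nxt <- i + dir
    if (nxt < 1 || nxt > n) break
    if (abs(ts_num[nxt] - ts_num[i]) > gap_s) break        # gap boundary
    if (sm[nxt] <= return_level) { i <- nxt; break }       # returned to base
    if (sm[nxt] > sm[i]) break                             # renewed rise
    i <- nxt
  }
  i
}

# truncate overlapping extents at the glucose minimum between the apexes
enforce_disjoint <- function(peaks, trace) {
  if (nrow(peaks) < 2) return(peaks)
  for (i in seq_len(nrow(peaks) - 1)) {
    if (peaks$end[i] >= peaks$start[i + 1]) {
      between <- trace$timestamp > peaks$apex[i] &
        trace$timestamp < peaks$apex[i + 1]
      idx <- which(between)
      cut <- idx[which.min(trace$glucose[idx])]
      peaks$end[i] <- trace$timestamp[cut]
      peaks$start[i + 1] <- trace$timestamp[cut]
    }
  }
  # a shared boundary sample is allowed to touch, not to overlap
  for (i in seq_len(nrow(peaks) - 1)) {
    if (peaks$end[i] > peaks$start[i + 1]) {
      peaks$end[i] <- peaks$start[i + 1]
    }
  }
  peaks
}

#' Per-day peak summaries
#'
#' For each local calendar day covered by the trace: number of peaks (by
#' apex time), total in-peak duration, and the in-peak fraction of sampled
#' time (sampled time = samples in the day times the nominal interval).
#'
#' @param trace a [glucose_trace()].
#' @param peaks result of [detect_peaks()] on that trace.
#' @return List with `per_day` (tibble: `day`, `n_peaks`,
#'   `in_peak_minutes`, `sampled_minutes`, `in_peak_fraction`) and the means
#'   `mean_peaks_per_day`, `mean_in_peak_minutes`, `mean_in_peak_fraction`.
#' @export
peak_summaries <- function(trace, peaks) {
  tz <- attr(trace, "tz") %||% "UTC"
  days <- trace_local_days(trace)
  step <- attr(trace, "nominal_interval")
  per_day <- lapply(split(seq_len(nrow(trace)), days), function(idx) {
    day <- days[idx[1]]
    day_start <- as.POSIXct(paste(day, "00:00:00"), tz = tz)
    day_end <- day_start + 86400
    apex_in <- peaks$apex >= day_start & peaks$apex < day_end
    overlap <- pmin(as.numeric(peaks$end), as.numeric(day_end)) -
      pmax(as.numeric(peaks$start), as.numeric(day_start))
    in_peak_min <- sum(pmax(overlap, 0)) / 60
    sampled_min <- length(idx) * step
    tibble(day = day, n_peaks = sum(apex_in), in_peak_minutes = in_peak_min,
           sampled_minutes = sampled_min,
           in_peak_fraction = in_peak_min / (length(idx) * step))
  })
  per_day <- bind_rows(per_day)
  list(per_day = per_day,
       mean_peaks_per_day = mean(per_day$n_peaks),
       mean_in_peak_minutes = mean(per_day$in_peak_minutes),
       mean_in_peak_fraction = mean(per_day$in_peak_fraction))
}

#' Match meal annotations to detected peaks
#'
#' Greedy chronological matching: each meal annotation, in time order, is
#' matched to the first still-unmatched peak whose start lies in
#' `[meal time - 15 min, meal time + max_lag]`; each peak matches at most
#' one meal.
#'
#' @param peaks result of [detect_peaks()].
#' @param events an [annotation_events()] tibble (only `kind == "meal"` rows
#'   are used).
#' @param max_lag latest allowed peak start after the meal, minutes.
#' @return List with `matches` (tibble: `meal_time`, `peak_start`,
#'   `lag_min`), `unmatched_meals` (POSIXct) and `unmatched_peaks` (row
#'   indices into `peaks`).
#' @export
match_peaks_to_events <- function(peaks, events, max_lag = 90) {
  meals <- sort(events$timestamp[events$kind == "meal"])
  used <- rep(FALSE, nrow(peaks))
  rows <- list()
  unmatched <- meals[0]
  for (m in seq_along(meals)) {
    lag <- as.numeric(difftime(peaks$start, meals[m], units = "mins"))
    ok <- which(!used & lag >= -15 & lag <= max_lag)
    if (length(ok) == 0) {
      unmatched <- c(unmatched, meals[m])
    } else {
      j <- ok[1]
      used[j] <- TRUE
      rows[[length(rows) + 1]] <- tibble(meal_time = meals[m],
                                         peak_start = peaks$start[j],
                                         lag_min = lag[j])
    }
  }
  list(matches = bind_rows(rows), unmatched_meals = unmatched,
       unmatched_peaks = which(!used))
}
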