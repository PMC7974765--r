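# Seeded synthetic-data generator: CGM traces with meal excursions, MTT
# segments, cross-over cohorts, scan behavior, and a full study bundle.
# It emulates the statistical structure the analysis assumes (15-min
# interstitial sampling, 8-h buffer, circadian drift, unimodal meal
# responses, scan fatigue, a tunable treatment effect on the MTT response);
# it is not a physiological insulin-glucose model.

#' Trace-generator parameters
#'
#' @param baseline_mean cohort mean fasting glucose, mg/dL.
#' @param baseline_sd_between_subject between-subject SD of the baseline,
#'   mg/dL.
#' @param circadian_amplitude amplitude of a 24-h sinusoid peaking at the
#'   dawn phase (08:00 local), mg/dL.
#' @param noise_sd independent per-sample sensor noise SD, mg/dL.
#' @param noise_ar1 optional lag-1 autocorrelation of the noise in `[0, 1)`.
#' @param sampling_interval minutes between samples.
#' @param seed integer seed (NULL leaves the RNG stream alone).
#' @return A list of class `trace_gen_params`.
#' @export
trace_gen_params <- function(baseline_mean = 95,
                             baseline_sd_between_subject = 10,
                             circadian_amplitude = 8, noise_sd = 5,
                             noise_ar1 = 0, sampling_interval = 15,
                             seed = NULL) {
  stopifnot(baseline_sd_between_subject >= 0, noise_sd >= 0,
            sampling_interval > 0, noise_ar1 >= 0, noise_ar1 < 1)
  structure(list(baseline_mean = baseline_mean,
                 baseline_sd_between_subject = baseline_sd_between_subject,
                 circadian_amplitude = circadian_amplitude,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1,
                 sampling_interval = sampling_interval, seed = seed),
            class = "trace_gen_params")
}

#' Meal-response parameters
#'
#' The meal impulse is a gamma-density-shaped unimodal curve: it rises to an
#' apex of `carbs_g * peak_height_per_g` mg/dL at `time_to_peak` minutes and
#' decays so that only 5% of the apex remains at `return_time` minutes. The
#' default 45 g of carbohydrates matches a standardized nutritional drink
#' used for meal-tolerance testing.
#'
#' @param carbs_g carbohydrate load in grams.
#' @param peak_height_per_g apex height per gram of carbohydrate, mg/dL/g.
#' @param time_to_peak minutes from intake to apex.
#' @param return_time minutes from intake until the excursion has essentially
#'   resolved.
#' @return A list of class `meal_response_params`.
#' @export
meal_response_params <- function(carbs_g = 45, peak_height_per_g = 1.2,
                                 time_to_peak = 45, return_time = 120) {
  stopifnot(time_to_peak < return_time, time_to_peak > 0,
            carbs_g >= 0, peak_height_per_g >= 0)
  structure(list(carbs_g = carbs_g, peak_height_per_g = peak_height_per_g,
                 time_to_peak = time_to_peak, return_time = return_time),
            class = "meal_response_params")
}

# Impulse value at `minutes` after intake. Normalized gamma-kernel form
# A * (u/m)^a * exp(a (1 - u/m)) with apex A at the mode m = time_to_peak;
# the exponent a is solved in closed form so the kernel equals 0.05 A at
# return_time.
meal_impulse <- function(minutes, params) {
  m <- params$time_to_peak
  r <- params$return_time / m
  a <- log(0.05) / log(r * exp(1 - r))
  apex <- params$carbs_g * params$peak_height_per_g
  u <- pmax(minutes, 0) / m
  ifelse(minutes <= 0, 0, apex * u^a * exp(a * (1 - u)))
}

#' Simulate a CGM glucose trace
#'
#' One sample per `sampling_interval`: subject baseline (drawn once per call
#' from the between-subject law) + circadian sinusoid + the sum of active
#' meal impulse responses + sensor noise. Values that would fall below
#' 40 mg/dL are clipped there (count kept in attribute `n_clipped`).
#'
#' @param params [trace_gen_params()].
#' @param duration_days length of the trace in days.
#' @param meals optional data frame with column `time` (POSIXct intake
#'   times) and optional columns `carbs_g` and `multiplier` (per-meal
#'   incremental-response scaling, default 1).
#' @param meal_params shared [meal_response_params()] for shape/height.
#' @param start trace start time (POSIXct, UTC).
#' @param subject_id identifier stamped on the trace.
#' @param tz local time zone for calendar-day metrics.
#' @return A [glucose_trace()]; attribute `truth` records the subject
#'   baseline and per-sample noiseless signal for generator-truth tests.
#' @export
simulate_trace <- function(params = trace_gen_params(), duration_days = 1,
                           meals = NULL, meal_params = meal_response_params(),
                           start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                           subject_id = "SIM1", tz = "UTC") {
  stopifnot(duration_days > 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  step_s <- params$sampling_interval * 60
  n <- floor(duration_days * 86400 / step_s)
  ts <- start + (seq_len(n) - 1) * step_s
  baseline <- params$baseline_mean +
    rnorm(1, 0, params$baseline_sd_between_subject)
  hour_local <- as.numeric(format(ts, "%H", tz = tz)) +
    as.numeric(format(ts, "%M", tz = tz)) / 60
  circ <- params$circadian_amplitude * cos(2 * pi * (hour_local - 8) / 24)
  signal <- baseline + circ
  if (!is.null(meals) && nrow(meals) > 0) {
    meals <- as_tibble(meals)
    if (!"carbs_g" %in% names(meals)) meals$carbs_g <- meal_params$carbs_g
    if (!"multiplier" %in% names(meals)) meals$multiplier <- 1
    for (i in seq_len(nrow(meals))) {
      mp <- meal_params
      mp$carbs_g <- meals$carbs_g[i]
      mins <- as.numeric(difftime(ts, meals$time[i], units = "mins"))
      signal <- signal + meals$multiplier[i] * meal_impulse(mins, mp)
    }
  }
  noise <- rnorm(n, 0, params$noise_sd)
  if (params$noise_ar1 > 0 && n > 1) {
    phi <- params$noise_ar1
    noise <- as.numeric(stats::filter(noise * sqrt(1 - phi^2), phi,
                                      method = "recursive"))
  }
  glucose <- signal + noise
  n_clipped <- sum(glucose < 40)
  glucose <- pmax(glucose, 40)
  out <- glucose_trace(tibble(timestamp = ts, glucose = glucose,
                              source = "cgm_scan"),
                       subject_id = subject_id,
                       nominal_interval = params$sampling_interval, tz = tz)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "truth") <- list(baseline = baseline, signal = signal)
  out
}

#' Simulate a single meal-tolerance-test segment
#'
#' Nine samples on the closed grid 0, 15, ..., 120 minutes after intake:
#' `baseline + effect_multiplier * impulse(t) + noise`. The incremental
#' response scales linearly with `effect_multiplier`, which is how a
#' treatment effect on glycemic control is injected.
#'
#' @param params [meal_response_params()].
#' @param effect_multiplier nonnegative scaling of the incremental response.
#' @param baseline fasting glucose at intake, mg/dL.
#' @param t0 intake time (POSIXct).
#' @param noise_sd per-sample noise SD, mg/dL (0 for a deterministic
#'   segment).
#' @param interval sampling interval in minutes.
#' @param subject_id identifier stamped on the segment.
#' @return A [glucose_trace()] with 9 samples.
#' @export
simulate_mtt_response <- function(params = meal_response_params(),
                                  effect_multiplier = 1, baseline = 95,
                                  t0 = as.POSIXct("2024-03-04 07:00:00",
                                                  tz = "UTC"),
                                  noise_sd = 0, interval = 15,
                                  subject_id = "SIM1") {
  stopifnot(effect_multiplier >= 0)
  mins <- seq(0, 120, by = interval)
  glucose <- baseline + effect_multiplier * meal_impulse(mins, params) +
    rnorm(length(mins), 0, noise_sd)
  glucose_trace(tibble(timestamp = t0 + mins * 60, glucose = pmax(glucose, 40),
                       source = "cgm_scan"),
                subject_id = subject_id, nominal_interval = interval)
}

#' Cross-over effect parameters
#'
#' @param delta_delta_mean mean treatment effect on the between-arm contrast
#'   of within-arm AUC changes, (mg/dL)*min.
#' @param delta_delta_sd between-subject SD of that contrast, (mg/dL)*min.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return A list of class `crossover_effect_params`.
#' @export
crossover_effect_params <- function(delta_delta_mean = 0,
                                    delta_delta_sd = 1228.43,
                                    n_subjects = 6, seed = NULL) {
  stopifnot(delta_delta_sd > 0, n_subjects >= 2)
  structure(list(delta_delta_mean = delta_delta_mean,
                 delta_delta_sd = delta_delta_sd,
                 n_subjects = n_subjects, seed = seed),
            class = "crossover_effect_params")
}

#' Simulate per-subject cross-over contrasts
#'
#' Draws each subject's between-arm contrast from a normal law with the
#' stated mean and SD, and constructs consistent within-arm AUC changes
#' (placebo-arm changes drawn on the scale seen in small MTT studies,
#' product-arm change = placebo change + contrast).
#'
#' @param params [crossover_effect_params()].
#' @return Tibble with columns `subject_id`, `delta_auc_placebo`,
#'   `delta_auc_product`, `delta_delta_auc`.
#' @export
simulate_crossover_cohort <- function(params = crossover_effect_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_subjects
  ddauc <- rnorm(n, params$delta_delta_mean, params$delta_delta_sd)
  placebo <- rnorm(n, 600, 600)
  tibble(subject_id = sprintf("S%d", seq_len(n)),
         delta_auc_placebo = placebo,
         delta_auc_product = placebo + ddauc,
         delta_delta_auc = ddauc)
}

#' Scan-behavior parameters
#'
#' Inter-scan intervals are log-normal around a median that drifts
#' multiplicatively per week of study (scan fatigue); with probability
#' `overshoot_prob` an interval instead exceeds the 8-hour device buffer,
#' losing the oldest data.
#'
#' @param median_interval_h median inter-scan interval, hours.
#' @param fatigue_drift multiplicative increase of the median per week.
#' @param overshoot_prob probability an interval exceeds the buffer.
#' @param interval_sdlog log-scale SD of the interval law (0 gives fixed
#'   intervals).
#' @param overshoot_hours range the overshooting intervals are drawn from.
#' @param seed integer seed.
#' @return A list of class `scan_behavior_params`.
#' @export
scan_behavior_params <- function(median_interval_h = 5, fatigue_drift = 1.1,
                                 overshoot_prob = 0.05, interval_sdlog = 0.35,
                                 overshoot_hours = c(8.5, 12), seed = NULL) {
  stopifnot(median_interval_h > 0, overshoot_prob >= 0, overshoot_prob <= 1,
            interval_sdlog >= 0, fatigue_drift > 0)
  structure(list(median_interval_h = median_interval_h,
                 fatigue_drift = fatigue_drift,
                 overshoot_prob = overshoot_prob,
                 interval_sdlog = interval_sdlog,
                 overshoot_hours = overshoot_hours, seed = seed),
            class = "scan_behavior_params")
}

#' Simulate flash-sensor scan downloads over a trace
#'
#' Draws scan times with a drifting median interval, then extracts from the
#' trace the samples each scan would have found in the device's 8-hour
#' buffer. Samples falling in no scan's window are thereby lost downstream;
#' a final scan at the trace end emulates device return.
#'
#' @param params [scan_behavior_params()].
#' @param trace a non-empty [glucose_trace()].
#' @param buffer_hours device memory depth, hours.
#' @return List of [scan_download()] objects.
#' @export
simulate_scan_records <- function(params = scan_behavior_params(), trace,
                                  buffer_hours = 8) {
  stopifnot(nrow(trace) > 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  span <- trace_span(trace)
  t0 <- span[1]; t_end <- span[2]
  # activation scan at wear start, final scan at device return
  scan_times <- as.numeric(t0)
  t <- as.numeric(t0)
  while (t < as.numeric(t_end)) {
    week <- floor((t - as.numeric(t0)) / (7 * 86400))
    med <- params$median_interval_h * params$fatigue_drift^week
    if (params$overshoot_prob > 0 && runif(1) < params$overshoot_prob) {
      iv <- runif(1, params$overshoot_hours[1], params$overshoot_hours[2])
    } else if (params$interval_sdlog == 0) {
      iv <- med
    } else {
      iv <- rlnorm(1, meanlog = log(med), sdlog = params$interval_sdlog)
    }
    t <- t + iv * 3600
    scan_times <- c(scan_times, min(t, as.numeric(t_end)))
  }
  scan_times <- unique(scan_times)
  lapply(scan_times, function(st) {
    st <- as.POSIXct(st, tz = "UTC", origin = "1970-01-01")
    win <- trace$timestamp > st - buffer_hours * 3600 & trace$timestamp <= st
    scan_download(st, trace[win, c("timestamp", "glucose", "source")],
                  buffer_hours = buffer_hours)
  })
}
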