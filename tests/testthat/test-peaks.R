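# Spike scoring, peak detection, summaries, annotation matching.

meal_day <- function(seed, carbs = c(55, 50, 60), noise_sd = 4,
                     hours = c(8, 12.5, 19)) {
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  simulate_trace(trace_gen_params(baseline_sd_between_subject = 0,
                                  noise_sd = noise_sd, seed = seed),
                 duration_days = 1,
                 meals = tibble::tibble(time = start + hours * 3600,
                                        carbs_g = carbs),
                 start = start)
}

test_that("spike scores are zero on constants and peak on an isolated spike", {
  expect_equal(spike_score(rep(7, 12), k = 3), rep(0, 12))
  s <- spike_score(c(0, 0, 0, 10, 0, 0, 0), k = 2)
  expect_equal(s[4], 10)
  expect_equal(s[3], 0)   # left max 0, right max 0 at the shoulder
  expect_equal(s[5], 0)
  expect_error(spike_score(1:4, k = 2), "too short")
})

test_that("flat traces with sensor noise yield no peaks", {
  tr <- simulate_trace(trace_gen_params(baseline_sd_between_subject = 0,
                                        noise_sd = 3, seed = 12),
                       duration_days = 1)
  expect_equal(nrow(detect_peaks(tr)), 0)
})

test_that("three well-separated meal bumps give three localized peaks", {
  tr <- meal_day(seed = 21)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 3)
  true_apexes <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC") +
    c(8, 12.5, 19) * 3600 + 45 * 60
  lag <- abs(as.numeric(difftime(pk$apex, true_apexes, units = "mins")))
  expect_true(all(lag <= 15))
  expect_true(all(pk$prominence >= 20))
})

test_that("bumps closer than the merge window collapse into one peak", {
  tr <- meal_day(seed = 22, carbs = c(60, 60), hours = c(12, 12.5),
                 noise_sd = 0)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
})

test_that("peak boundaries and scores are translation invariant", {
  tr <- meal_day(seed = 23)
  shifted <- glucose_trace(tibble::tibble(timestamp = tr$timestamp,
                                          glucose = tr$glucose + 60),
                           subject_id = "T1")
  p1 <- detect_peaks(tr)
  p2 <- detect_peaks(shifted)
  expect_equal(p2$start, p1$start)
  expect_equal(p2$apex, p1$apex)
  expect_equal(p2$end, p1$end)
  expect_equal(p2$score, p1$score)
  expect_equal(p2$prominence, p1$prominence)
})

test_that("detected peaks are sorted and pairwise disjoint", {
  for (seed in 31:40) {
    pk <- detect_peaks(meal_day(seed, carbs = c(55, 45, 60, 50, 65),
                                hours = c(7, 10, 13, 16, 19)))
    if (nrow(pk) < 2) next
    expect_true(all(diff(as.numeric(pk$apex)) > 0))
    expect_true(all(pk$start <= pk$apex & pk$apex <= pk$end))
    expect_true(all(as.numeric(pk$start[-1]) >=
                      as.numeric(pk$end[-nrow(pk)])))
  }
})

test_that("per-day summaries report counts and in-peak fractions", {
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  day <- simulate_trace(trace_gen_params(baseline_sd_between_subject = 0,
                                         noise_sd = 0, seed = 1),
                        duration_days = 1, start = start)
  p_start <- start + 10 * 3600
  p_apex <- start + 10.75 * 3600
  p_end <- start + 11.5 * 3600
  one_peak <- tibble::tibble(start = p_start, apex = p_apex, end = p_end,
                             apex_glucose = 150, local_baseline = 95,
                             prominence = 55, score = 20)
  s <- peak_summaries(day, one_peak)
  expect_equal(s$per_day$n_peaks, 1)
  expect_equal(s$mean_in_peak_minutes, 90)
  expect_equal(s$mean_in_peak_fraction, 90 / 1440)
  none <- peak_summaries(day, one_peak[0, ])
  expect_equal(none$mean_in_peak_fraction, 0)
  expect_equal(none$mean_peaks_per_day, 0)
})

test_that("meals match peaks greedily within the lag window", {
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  p_start <- start + (12 + 20 / 60) * 3600
  peaks <- tibble::tibble(start = p_start, apex = start + 13 * 3600,
                          end = start + 14 * 3600,
                          apex_glucose = 160, local_baseline = 100,
                          prominence = 60, score = 25)
  meals <- annotation_events(tibble::tibble(
    subject_id = "T1", timestamp = start + 12 * 3600, kind = "meal",
    payload = "photo", value = NA_real_))
  m <- match_peaks_to_events(peaks, meals)
  expect_equal(nrow(m$matches), 1)
  expect_equal(m$matches$lag_min, 20)

  # a delayed response: matched at the default 90-min lag, not at 60
  late_meal <- annotation_events(tibble::tibble(
    subject_id = "T1", timestamp = start + (12 + 20 / 60) * 3600 - 70 * 60,
    kind = "meal", payload = "photo", value = NA_real_))
  expect_equal(nrow(match_peaks_to_events(peaks, late_meal,
                                          max_lag = 90)$matches), 1)
  m60 <- match_peaks_to_events(peaks, late_meal, max_lag = 60)
  expect_equal(nrow(m60$matches), 0)
  expect_length(m60$unmatched_meals, 1)

  # two meals, one peak: the earlier meal wins
  two <- annotation_events(tibble::tibble(
    subject_id = "T1", timestamp = start + c(12, 12.25) * 3600,
    kind = "meal", payload = "photo", value = NA_real_))
  m2 <- match_peaks_to_events(peaks, two)
  expect_equal(m2$matches$meal_time, start + 12 * 3600)
  expect_length(m2$unmatched_meals, 1)
})
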