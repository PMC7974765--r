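# Synthetic-data generator: sampling grid, meal impulse, cohort law,
# scan behavior.

quiet_params <- function(seed = NULL, noise_sd = 0) {
  trace_gen_params(baseline_sd_between_subject = 0, circadian_amplitude = 0,
                   noise_sd = noise_sd, seed = seed)
}

test_that("one day at 15-minute sampling yields 96 samples", {
  tr <- simulate_trace(quiet_params(seed = 1), duration_days = 1)
  expect_equal(nrow(tr), 96)
  expect_equal(as.numeric(diff(tr$timestamp), units = "mins"),
               rep(15, 95))
})

test_that("without noise, circadian term or meals the trace is flat", {
  tr <- simulate_trace(quiet_params(seed = 1), duration_days = 1)
  expect_equal(tr$glucose, rep(95, 96))
})

test_that("a single meal peaks at time_to_peak with the closed-form apex", {
  meal_t <- t_origin
  tr <- simulate_trace(quiet_params(seed = 1), duration_days = 1,
                       meals = tibble::tibble(time = meal_t),
                       start = t_origin - 6 * 3600)
  apex_i <- which.max(tr$glucose)
  expect_equal(as.numeric(difftime(tr$timestamp[apex_i], meal_t,
                                   units = "mins")), 45)
  expect_equal(max(tr$glucose), 95 + 45 * 1.2, tolerance = 1e-12)
})

test_that("MTT segments have 9 samples and scale linearly with the effect", {
  seg1 <- simulate_mtt_response(effect_multiplier = 1, baseline = 95)
  seg07 <- simulate_mtt_response(effect_multiplier = 0.7, baseline = 95)
  seg0 <- simulate_mtt_response(effect_multiplier = 0, baseline = 95)
  expect_equal(nrow(seg1), 9)
  a1 <- incremental_auc(seg1, seg1$timestamp[1])$auc
  a07 <- incremental_auc(seg07, seg07$timestamp[1])$auc
  a0 <- incremental_auc(seg0, seg0$timestamp[1])$auc
  expect_equal(a0, 0)
  expect_equal(a07, 0.7 * a1, tolerance = 1e-9)
})

test_that("cohort contrasts follow the stated normal law and are seeded", {
  p <- crossover_effect_params(delta_delta_mean = 0, delta_delta_sd = 1000,
                               n_subjects = 400, seed = 42)
  tab <- simulate_crossover_cohort(p)
  expect_equal(nrow(tab), 400)
  expect_lt(abs(mean(tab$delta_delta_auc)), 3 * 1000 / sqrt(400))
  expect_equal(tab$delta_delta_auc,
               tab$delta_auc_product - tab$delta_auc_placebo)
  tab2 <- simulate_crossover_cohort(p)
  expect_identical(tab, tab2)
  # pilot-scale parameterization stays finite and well-formed
  pilot <- simulate_crossover_cohort(crossover_effect_params(
    delta_delta_mean = -1546.73, delta_delta_sd = 1228.43,
    n_subjects = 6, seed = 1))
  expect_equal(nrow(pilot), 6)
  expect_true(all(is.finite(pilot$delta_delta_auc)))
})

test_that("regular scans within the buffer reproduce the full trace", {
  tr <- simulate_trace(quiet_params(seed = 5, noise_sd = 3),
                       duration_days = 2)
  sc <- simulate_scan_records(scan_behavior_params(
    median_interval_h = 6, fatigue_drift = 1, interval_sdlog = 0,
    overshoot_prob = 0, seed = 9), tr)
  m <- merge_scan_downloads(sc, subject_id = "SIM1")
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$glucose, tr$glucose)
})

test_that("a 10-hour inter-scan interval loses exactly the first 2 hours", {
  tr <- simulate_trace(quiet_params(seed = 5, noise_sd = 3),
                       duration_days = 0.5)
  sc <- simulate_scan_records(scan_behavior_params(
    median_interval_h = 10, fatigue_drift = 1, interval_sdlog = 0,
    overshoot_prob = 0, seed = 9), tr)
  # activation scan, one 10-h interval, device-return scan
  m <- merge_scan_downloads(sc, subject_id = "SIM1")
  # the scan at +10 h holds (2 h, 10 h]; the 8 samples in (0 h, 2 h]
  # (15-min spacing) are unrecoverable
  lost <- setdiff(as.numeric(tr$timestamp), as.numeric(m$timestamp))
  expect_equal(length(lost), 8)
  expect_true(all(lost > as.numeric(tr$timestamp[1]) &
                    lost <= as.numeric(tr$timestamp[1]) + 2 * 3600))
})

test_that("fatigue drift lengthens the median inter-scan interval", {
  tr <- simulate_trace(quiet_params(seed = 2, noise_sd = 3),
                       duration_days = 28)
  diff_by_seed <- vapply(1:10, function(s) {
    sc <- simulate_scan_records(scan_behavior_params(
      median_interval_h = 5, fatigue_drift = 1.2, overshoot_prob = 0,
      seed = s), tr)
    gaps <- scan_gap_stats(sort(do.call(c, lapply(sc, `[[`, "scan_time"))))
    med <- gaps$median_by_week
    med[length(med)] - med[1]
  }, numeric(1))
  expect_gt(mean(diff_by_seed), 0)
})

test_that("all generators are deterministic under a fixed seed", {
  p <- trace_gen_params(seed = 7)
  tr1 <- simulate_trace(p, 1)
  tr2 <- simulate_trace(p, 1)
  expect_identical(tr1$glucose, tr2$glucose)
  sp <- scan_behavior_params(seed = 3)
  s1 <- simulate_scan_records(sp, tr1)
  s2 <- simulate_scan_records(sp, tr1)
  expect_identical(lapply(s1, `[[`, "scan_time"),
                   lapply(s2, `[[`, "scan_time"))
})

test_that("sub-floor glucose is clipped at 40 mg/dL and counted", {
  p <- trace_gen_params(baseline_mean = 42, baseline_sd_between_subject = 0,
                        circadian_amplitude = 0, noise_sd = 10, seed = 8)
  tr <- simulate_trace(p, 1)
  expect_true(all(tr$glucose >= 40))
  expect_equal(attr(tr, "n_clipped"), sum(tr$glucose == 40))
  expect_gt(attr(tr, "n_clipped"), 0)
})
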