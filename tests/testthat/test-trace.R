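# Trace parsing, buffer-download merging, window slicing.

write_trace_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("subject_id,timestamp,glucose_mgdl,source", rows), path)
  path
}

test_that("parse_trace_table reads, filters and sorts the canonical CSV", {
  path <- write_trace_csv(c(
    "A,2024-03-04T08:30:00,110,cgm_scan",
    "B,2024-03-04T08:00:00,95,cgm_scan",
    "A,2024-03-04T08:00:00,100,cgm_scan",
    "A,2024-03-04T08:15:00,105,fingerstick"))
  tr <- parse_trace_table(path, "A")
  expect_s3_class(tr, "glucose_trace")
  expect_equal(nrow(tr), 3)
  expect_false(is.unsorted(tr$timestamp))
  expect_equal(tr$glucose, c(100, 105, 110))
  expect_equal(attr(tr, "subject_id"), "A")
})

test_that("parse_trace_table rejects corrupt rows with informative errors", {
  bad_ts <- write_trace_csv("A,not-a-time,100,cgm_scan")
  expect_error(parse_trace_table(bad_ts, "A"), "malformed timestamp")
  conflict <- write_trace_csv(c("A,2024-03-04T08:00:00,100,cgm_scan",
                                "A,2024-03-04T08:00:00,101,cgm_scan"))
  expect_error(parse_trace_table(conflict, "A"), "conflicting glucose")
  oob <- write_trace_csv("A,2024-03-04T08:00:00,612,cgm_scan")
  expect_error(parse_trace_table(oob, "A"), "plausible bounds")
  # identical duplicates collapse silently
  dup <- write_trace_csv(c("A,2024-03-04T08:00:00,100,cgm_scan",
                           "A,2024-03-04T08:00:00,100,cgm_scan"))
  expect_equal(nrow(parse_trace_table(dup, "A")), 1)
})

test_that("merging overlapping downloads deduplicates to a single trace", {
  full <- make_trace(90 + seq_len(48), start = t_origin)  # 12 h of samples
  d1 <- scan_download(t_origin + 8 * 3600 - 60,
                      full[full$timestamp <= t_origin + 8 * 3600 - 60, ])
  d2 <- scan_download(t_origin + 12 * 3600,
                      full[full$timestamp > t_origin + 4 * 3600, ])
  m <- merge_scan_downloads(list(d1, d2), subject_id = "T1")
  expect_equal(nrow(m), nrow(full))
  expect_equal(m$glucose, full$glucose)
  expect_equal(nrow(trace_gaps(m)), 0)
})

test_that("scans further apart than the buffer leave a reported gap", {
  # samples every 15 min over 9 h; scans at 0 h (trivial) and 9 h
  full <- make_trace(rep(100, 37), start = t_origin)
  t_scan1 <- t_origin
  t_scan2 <- t_origin + 9 * 3600
  d1 <- scan_download(t_scan1, full[full$timestamp <= t_scan1, ])
  d2 <- scan_download(t_scan2, full[full$timestamp > t_scan2 - 8 * 3600 &
                                      full$timestamp <= t_scan2, ])
  m <- merge_scan_downloads(list(d1, d2))
  gaps <- trace_gaps(m)
  expect_equal(nrow(gaps), 1)
  expect_equal(as.numeric(difftime(gaps$end, gaps$start, units = "hours")), 1)
  # samples in (0 h, 1 h] after the first scan are genuinely absent
  lost <- full$timestamp > t_scan1 & full$timestamp <= t_scan1 + 3600
  expect_equal(nrow(m), nrow(full) - sum(lost))
  expect_false(any(m$timestamp %in% full$timestamp[lost]))
})

test_that("merging is idempotent and a single download is the identity", {
  full <- make_trace(100 + sin(1:32))
  d <- scan_download(t_origin + 31 * 15 * 60, full)
  m1 <- merge_scan_downloads(list(d))
  expect_equal(m1$glucose, full$glucose)
  d_again <- scan_download(t_origin + 31 * 15 * 60, m1)
  m2 <- merge_scan_downloads(list(d, d_again))
  expect_equal(m2$glucose, m1$glucose)
  expect_equal(m2$timestamp, m1$timestamp)
})

test_that("conflicting glucose across downloads is an integrity error", {
  d1 <- scan_download(t_origin, tibble::tibble(timestamp = t_origin,
                                               glucose = 100))
  d2 <- scan_download(t_origin + 60, tibble::tibble(timestamp = t_origin,
                                                    glucose = 104))
  expect_error(merge_scan_downloads(list(d1, d2)), "conflicting glucose")
})

test_that("slice_window uses closed bounds: nine samples per 2-h window", {
  day <- make_trace(rep(100, 96), start = t_origin, interval = 15)
  w <- slice_window(day, t_origin, t_origin + 2 * 3600)
  expect_equal(nrow(w), 9)
  expect_equal(nrow(slice_window(day, t_origin - 86400 * 2,
                                 t_origin - 86400)), 0)
  span <- trace_span(day)
  full <- slice_window(day, span[1], span[2])
  expect_equal(full$timestamp, day$timestamp)
  expect_equal(full$glucose, day$glucose)
})

test_that("trace invariants are enforced at construction", {
  expect_error(make_trace(c(100, 0)), "plausible bounds")
  expect_error(make_trace(c(100, 501)), "plausible bounds")
  expect_error(glucose_trace(tibble::tibble(
    timestamp = c(t_origin, t_origin), glucose = c(100, 100))),
    "duplicate")
})
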