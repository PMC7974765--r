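# End-to-end study driver: full synthetic-study generator and the
# per-subject + cohort report.

#' Simulate a complete cross-over study bundle
#'
#' Generates, for `n_subjects`, a cross-over design (two 14-day periods,
#' arms in alternating order across subjects, 4-day washout), a full-study
#' CGM trace with three daily meals, four fasted meal-tolerance tests (at
#' the beginning and end of each period, 07:00 local, breakfast skipped on
#' test days so the fasting window stays quiet), and an app event log
#' (MTT start markers, meal photos logged with the stated probability,
#' occasional exercise and fingerstick entries). The treatment effect is a
#' multiplier on the incremental response of the product-period-end MTT
#' meal: values below 1 emulate improved glycemic control on the product.
#'
#' @param n_subjects number of subjects.
#' @param product_effect multiplier applied to the MTT meal response at the
#'   end of the product period (1 = no effect).
#' @param trace_params [trace_gen_params()] shared by all subjects.
#' @param meal_params [meal_response_params()] for the standardized MTT
#'   meal (45 g carbohydrates).
#' @param meal_log_prob probability a meal is annotated in the app.
#' @param start study start (POSIXct, local midnight).
#' @param drop_mtt_for subject ids whose final MTT marker is withheld from
#'   the event log (to exercise incomplete-subject handling).
#' @param seed integer seed.
#' @return List with elements `traces` (named list of [glucose_trace()]),
#'   `events` (one [annotation_events()] tibble), `designs` (named list of
#'   [study_design()]), and `truth` (per-subject MTT schedule and
#'   multipliers).
#' @export
simulate_study <- function(n_subjects = 6, product_effect = 0.7,
                           trace_params = trace_gen_params(),
                           meal_params = meal_response_params(),
                           meal_log_prob = 0.8,
                           start = as.POSIXct("2024-03-04 00:00:00",
                                              tz = "UTC"),
                           drop_mtt_for = character(0), seed = 1) {
  set.seed(seed)
  traces <- list(); designs <- list(); truth <- list()
  events <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%d", s)
    arms <- if (s %% 2 == 1) c("product", "placebo") else c("placebo", "product")
    p1 <- c(start, start + 14 * 86400)
    p2 <- c(start + 18 * 86400, start + 32 * 86400)
    designs[[sid]] <- study_design(
      sid,
      periods = tibble(arm = arms, start = c(p1[1], p2[1]),
                       end = c(p1[2], p2[2])),
      washouts = tibble(start = p1[2], end = p2[1]))
    mtt_days <- as.numeric(difftime(c(p1, p2), start, units = "days"))
    mtt_times <- start + mtt_days * 86400 + 7 * 3600
    mtt_labels <- paste0(rep(c("begin_", "end_"), 2), rep(arms, each = 2))
    mtt_mult <- ifelse(mtt_labels == "end_product", product_effect, 1)

    days <- 0:32
    meal_rows <- list()
    for (d in days) {
      is_mtt_day <- d %in% mtt_days
      times_h <- if (is_mtt_day) c(12.5, 19) else c(8, 12.5, 19)
      for (h in times_h) {
        meal_rows[[length(meal_rows) + 1]] <-
          tibble(time = start + d * 86400 + h * 3600,
                 carbs_g = min(90, max(20, rnorm(1, 50, 10))),
                 multiplier = 1, is_mtt = FALSE)
      }
    }
    meals <- bind_rows(meal_rows)
    meals <- bind_rows(meals,
                       tibble(time = mtt_times, carbs_g = meal_params$carbs_g,
                              multiplier = mtt_mult, is_mtt = TRUE))
    meals <- meals[order(meals$time), ]
    tp <- trace_params
    tp$seed <- NULL  # one RNG stream for the whole study
    traces[[sid]] <- simulate_trace(tp, duration_days = 32.5,
                                    meals = meals,
                                    meal_params = meal_params,
                                    start = start, subject_id = sid)
    keep_mtt <- if (sid %in% drop_mtt_for) mtt_times[-4] else mtt_times
    ev <- list(tibble(subject_id = sid, timestamp = keep_mtt,
                      kind = "mtt_start", payload = "standardized meal",
                      value = NA_real_))
    logged <- meals[!meals$is_mtt & runif(nrow(meals)) < meal_log_prob, ]
    if (nrow(logged) > 0) {
      ev[[2]] <- tibble(subject_id = sid, timestamp = logged$time,
                        kind = "meal", payload = "photo", value = NA_real_)
    }
    ex_days <- days[runif(length(days)) < 0.3]
    if (length(ex_days) > 0) {
      ev[[3]] <- tibble(subject_id = sid,
                        timestamp = start + ex_days * 86400 + 17.5 * 3600,
                        kind = "exercise", payload = "logged workout",
                        value = NA_real_)
    }
    fs_days <- days[runif(length(days)) < 0.3]
    if (length(fs_days) > 0) {
      fs_t <- start + fs_days * 86400 + 9 * 3600
      fs_v <- approx(as.numeric(traces[[sid]]$timestamp),
                     traces[[sid]]$glucose, xout = as.numeric(fs_t),
                     rule = 2)$y
      ev[[4]] <- tibble(subject_id = sid, timestamp = fs_t,
                        kind = "fingerstick", payload = "",
                        value = round(fs_v))
    }
    events[[sid]] <- bind_rows(ev)
    truth[[sid]] <- list(mtt_times = mtt_times, mtt_labels = mtt_labels,
                         mtt_multipliers = mtt_mult, arms = arms)
  }
  list(traces = traces, events = annotation_events(bind_rows(events)),
       designs = designs, truth = truth)
}

#' Write a simulated study to the canonical on-disk formats
#'
#' Writes `traces.csv` (trace table), `events.csv` (annotation log) and
#' `design.json` (cross-over designs) into `dir`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  tr <- bind_rows(lapply(sim$traces, function(x) {
    tibble(subject_id = attr(x, "subject_id"), timestamp = iso(x$timestamp),
           glucose_mgdl = x$glucose, source = x$source)
  }))
  paths <- file.path(dir, c("traces.csv", "events.csv", "design.json"))
  utils::write.csv(tr, paths[1], row.names = FALSE)
  ev <- sim$events
  ev$timestamp <- iso(ev$timestamp)
  utils::write.csv(ev, paths[2], row.names = FALSE)
  dj <- lapply(unname(sim$designs), function(d) {
    list(subject_id = d$subject_id,
         periods = lapply(seq_len(nrow(d$periods)), function(i) {
           list(arm = d$periods$arm[i], start = iso(d$periods$start[i]),
                end = iso(d$periods$end[i]))
         }),
         washouts = lapply(seq_len(nrow(d$washouts)), function(i) {
           list(start = iso(d$washouts$start[i]),
                end = iso(d$washouts$end[i]))
         }))
  })
  jsonlite::write_json(dj, paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

# label the four MTT markers of one subject from the design: for each
# period, the marker nearest the period start (within 2 days) is the
# begin test, nearest the end the end test
assign_mtt_labels <- function(mtt_times, design, tol_days = 2) {
  out <- tibble(t0 = mtt_times[0], label = character(0))
  used <- rep(FALSE, length(mtt_times))
  for (i in seq_len(nrow(design$periods))) {
    arm <- design$periods$arm[i]
    for (endpoint in c("start", "end")) {
      ref <- design$periods[[endpoint]][i]
      d <- abs(as.numeric(difftime(mtt_times, ref, units = "days")))
      ok <- which(!used & d <= tol_days)
      if (length(ok) == 0) next
      j <- ok[which.min(d[ok])]
      used[j] <- TRUE
      lab <- paste0(if (endpoint == "start") "begin_" else "end_", arm)
      out <- bind_rows(out, tibble(t0 = mtt_times[j], label = lab))
    }
  }
  out
}

#' Run the full study analysis and build a structured report
#'
#' Per subject: the four labelled MTT incremental AUCs with fasting
#' pre-checks, the cross-over contrast, peak summaries, compliance metrics,
#' and glycemic metrics. Subjects lacking one of the four MTT markers (or
#' with an unanalyzable MTT window) are flagged incomplete and excluded
#' from the cohort test, which is the exact one-sided signed-rank test on
#' the per-subject contrasts. An optional Monte-Carlo power estimate for a
#' future study is included when requested via `config$power`.
#'
#' @param traces named list of [glucose_trace()] keyed by subject.
#' @param events one [annotation_events()] tibble for all subjects.
#' @param designs named list of [study_design()] keyed by subject.
#' @param scans optional named list of POSIXct scan-time vectors.
#' @param config list of options: `convention` (`"positive_only"`),
#'   `alternative` (`"less"`), `alpha` (0.05), `peak_params`, `thresholds`,
#'   `fasting_hours` (6), `excursion_limit` (25), and optionally `power =
#'   list(n_subjects, n_sim, seed)`.
#' @return A `study_report` list with `schema_version`, `generated`,
#'   `subjects` and `cohort` blocks.
#' @export
run_study_report <- function(traces, events, designs, scans = NULL,
                             config = list()) {
  cfg <- utils::modifyList(
    list(convention = "positive_only", alternative = "less", alpha = 0.05,
         peak_params = peak_params(), thresholds = metric_thresholds(),
         fasting_hours = 6, excursion_limit = 25, power = NULL),
    config)
  subjects <- list()
  contrasts <- list()
  for (sid in names(designs)) {
    design <- designs[[sid]]
    trace <- traces[[sid]]
    ev <- events[events$subject_id == sid, ]
    block <- list(subject_id = sid, complete = FALSE, reason = NULL)
    mtt_marks <- ev$timestamp[ev$kind == "mtt_start"]
    labelled <- assign_mtt_labels(mtt_marks, design)
    if (nrow(labelled) < 4) {
      block$reason <- sprintf("only %d of 4 MTT markers found",
                              nrow(labelled))
    } else {
      mtts <- vector("list", 4)
      fasting <- vector("list", 4)
      failed <- NULL
      peaks <- tryCatch(detect_peaks(trace, cfg$peak_params),
                        error = function(e) NULL)
      for (i in seq_len(4)) {
        res <- tryCatch(
          incremental_auc(trace, labelled$t0[i],
                          convention = cfg$convention,
                          label = labelled$label[i]),
          error = function(e) conditionMessage(e))
        if (is.character(res)) { failed <- res; break }
        mtts[[i]] <- res
        fc <- fasting_precheck(trace, labelled$t0[i],
                               fasting_hours = cfg$fasting_hours,
                               excursion_limit = cfg$excursion_limit,
                               peaks = peaks)
        fasting[[i]] <- list(label = labelled$label[i],
                             verdict = fc$verdict,
                             max_excursion = fc$max_excursion)
      }
      if (!is.null(failed)) {
        block$reason <- failed
      } else {
        block$complete <- TRUE
        block$mtt <- lapply(mtts, function(r) {
          list(label = r$label, t0 = format(r$t0, "%Y-%m-%dT%H:%M:%SZ"),
               baseline_glucose = r$baseline_glucose, auc = r$auc,
               n_points_used = r$n_points_used,
               interpolated = r$interpolated, convention = r$convention)
        })
        block$fasting_checks <- fasting
        ctr <- crossover_contrasts(mtts, design)
        contrasts[[sid]] <- ctr
        block$contrast <- as.list(ctr)
      }
    }
    if (!is.null(trace)) {
      pk <- tryCatch(detect_peaks(trace, cfg$peak_params),
                     error = function(e) NULL)
      if (!is.null(pk)) {
        ps <- peak_summaries(trace, pk)
        block$peaks <- list(n_peaks = nrow(pk),
                            mean_peaks_per_day = ps$mean_peaks_per_day,
                            mean_in_peak_minutes = ps$mean_in_peak_minutes,
                            mean_in_peak_fraction = ps$mean_in_peak_fraction)
      }
      block$metrics <- subject_summary(trace, cfg$thresholds)
      block$metrics$time_in_range <- time_in_range(trace, cfg$thresholds)
      span_days <- max(1, ceiling(as.numeric(difftime(
        design$periods$end[nrow(design$periods)], design$periods$start[1],
        units = "days"))))
      ar <- annotation_rate_stats(ev, span_days,
                                  start = as.Date(design$periods$start[1]))
      block$compliance <- list(mean_logs_per_day = ar$mean_per_day,
                               var_mean_ratio = ar$var_mean_ratio,
                               weekly_trend = ar$weekly_trend)
      if (!is.null(scans[[sid]])) {
        sg <- scan_gap_stats(scans[[sid]])
        block$compliance$scan_gaps <-
          list(n_intervals = length(sg$intervals),
               n_over_limit = sg$n_over_limit, data_lost_h = sg$data_lost,
               trend = sg$trend)
      }
    }
    subjects[[sid]] <- block
  }
  cohort <- list(n_subjects = length(designs),
                 n_complete = length(contrasts))
  if (length(contrasts) >= 1) {
    ddauc <- bind_rows(contrasts)$delta_delta_auc
    test <- exact_wilcoxon_signed_rank(ddauc, alternative = cfg$alternative)
    cohort$signed_rank <- list(w_plus = test$w_plus,
                               n_effective = test$n_effective,
                               p_value = test$p_value,
                               alternative = test$alternative,
                               method = test$method)
    cohort$delta_delta_auc <- ddauc
  }
  if (!is.null(cfg$power)) {
    neg <- cohort$delta_delta_auc[cohort$delta_delta_auc < 0]
    eff <- if (length(neg)) mean(neg) else mean(cohort$delta_delta_auc)
    pw <- power_by_simulation(
      effect_mean = eff, effect_sd = sd(cohort$delta_delta_auc),
      n_subjects = cfg$power$n_subjects %||% 35,
      alpha = cfg$alpha, alternative = cfg$alternative,
      n_sim = cfg$power$n_sim %||% 20000, seed = cfg$power$seed)
    cohort$power <- list(n_subjects = pw$n_subjects, power = pw$power,
                         mc_se = pw$mc_se, effect_mean = pw$effect_mean,
                         effect_sd = pw$effect_sd, n_sim = pw$n_sim)
  }
  structure(list(schema_version = "1.0",
                 generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"),
                 subjects = subjects, cohort = cohort),
            class = "study_report")
}

#' Write a study report as JSON
#'
#' @param report a [run_study_report()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(path)
}
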