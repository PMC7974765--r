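# Shared fixtures and independent oracles.

t_origin <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")

make_trace <- function(values, start = t_origin, interval = 15,
                       subject = "T1") {
  glucose_trace(tibble::tibble(
    timestamp = start + (seq_along(values) - 1) * interval * 60,
    glucose = values), subject_id = subject, nominal_interval = interval)
}

# Independent integration oracle: refine the piecewise-linear increment
# curve and apply the midpoint rectangle rule (exact for linear pieces when
# rectangle edges align with the grid), coded without the trapezoid formula.
midpoint_refined_auc <- function(values, step = 15,
                                 convention = "positive_only",
                                 refine = 8) {
  inc <- values - values[1]
  if (convention == "positive_only") inc <- pmax(inc, 0)
  xs <- (seq_along(values) - 1) * step
  width <- step / refine
  mids <- seq(width / 2, max(xs) - width / 2, by = width)
  heights <- stats::approx(xs, inc, xout = mids)$y
  sum(heights) * width
}

# Independent signed-rank oracle: explicit enumeration of every sign
# assignment of the observed (mid-)ranks; n must be small.
brute_force_signed_rank <- function(values, alternative = "less") {
  values <- values[values != 0]
  n <- length(values)
  stopifnot(n <= 12)
  r <- rank(abs(values))
  w_obs <- sum(r[values > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  switch(alternative,
         less = mean(w_all <= w_obs + 1e-12),
         greater = mean(w_all >= w_obs - 1e-12),
         two_sided = min(1, 2 * min(mean(w_all <= w_obs + 1e-12),
                                    mean(w_all >= w_obs - 1e-12))))
}

# Table of printed per-subject MTT contrasts from the motivating six-subject
# pilot (baseline AUC and within-arm AUC changes, (mg/dL)*min).
pilot_table <- tibble::tibble(
  subject_id = c("6", "3", "5", "4", "1", "2"),
  baseline_auc = c(265.3, 737.0, 834.8, 1557.6, 2084.2, 3931.8),
  delta_auc_placebo = c(1035.1, 1027.1, 102.8, 427.7, -221.6, 1309.1),
  delta_auc_product = c(1683.2, 1598.3, 552.8, -933.0, -1213.9, -978.1))
pilot_table$delta_delta_auc <-
  pilot_table$delta_auc_product - pilot_table$delta_auc_placebo

# Four labelled MTT AUC rows per subject consistent with the printed
# within-arm changes (begin values are arbitrary; only changes matter).
pilot_mtt_rows <- function() {
  do.call(rbind, lapply(seq_len(nrow(pilot_table)), function(i) {
    b <- pilot_table$baseline_auc[i]
    tibble::tibble(
      subject_id = pilot_table$subject_id[i],
      label = c("begin_placebo", "end_placebo", "begin_product",
                "end_product"),
      auc = c(b, b + pilot_table$delta_auc_placebo[i],
              b, b + pilot_table$delta_auc_product[i]))
  }))
}
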