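# Exact one-sample Wilcoxon signed-rank test and Monte-Carlo power.
#
# The small-n regime of a pilot cross-over study (n = 6 paired contrasts)
# needs the exact null distribution, including under mid-ranked ties, which
# table-based implementations do not provide. The exact distribution is the
# enumeration of all 2^n sign assignments of the ranked absolute values,
# computed by convolution over the (doubled, hence integer) ranks.

#' Exact Wilcoxon signed-rank test
#'
#' One-sample signed-rank test of symmetry about zero. Zeros are dropped;
#' absolute values are ranked with mid-ranks for ties; `w_plus` is the sum of
#' ranks attached to positive values. For `n_effective <= exact_max_n` the
#' p-value comes from the exact enumeration of all `2^n` sign assignments
#' (exact even under ties); for larger n a normal approximation with
#' tie-corrected variance and continuity correction is used and recorded in
#' `method`.
#'
#' With `alternative = "less"` (a one-sided test that the values are shifted
#' below zero) the p-value is `P(W+ <= w_plus)` under the null.
#'
#' @param values numeric vector of paired differences/contrasts.
#' @param alternative `"less"`, `"greater"`, or `"two_sided"`.
#' @param exact_max_n largest `n_effective` for which the exact distribution
#'   is enumerated (default 20).
#' @return An object of class `signed_rank_result` with fields `w_plus`,
#'   `n_effective`, `p_value`, `alternative`, `method`.
#' @export
exact_wilcoxon_signed_rank <- function(values,
                                       alternative = c("less", "greater",
                                                       "two_sided"),
                                       exact_max_n = 20) {
  alternative <- match.arg(alternative)
  values <- values[values != 0]
  n <- length(values)
  if (n == 0) {
    stop("degenerate input: all values are zero", call. = FALSE)
  }
  r <- rank(abs(values))
  w_plus <- sum(r[values > 0])
  if (n <= exact_max_n) {
    method <- "exact_enumeration"
    d2 <- round(2 * r)              # doubled ranks are integers even at ties
    cdf <- signed_rank_doubled_pmf(d2)
    total <- sum(d2)
    w2 <- round(2 * w_plus)
    p_less <- sum(cdf[seq_len(w2 + 1)])          # P(2 W+ <= w2)
    p_greater <- sum(cdf[(w2 + 1):(total + 1)])  # P(2 W+ >= w2)
  } else {
    method <- "normal_approx"
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p_less <- pnorm((w_plus + 0.5 - mu) / sigma)
    p_greater <- pnorm((w_plus - 0.5 - mu) / sigma, lower.tail = FALSE)
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  structure(list(w_plus = w_plus, n_effective = n, p_value = p,
                 alternative = alternative, method = method),
            class = "signed_rank_result")
}

# Null pmf of 2*W+ over the grid 0..sum(d2), as a probability vector of
# length sum(d2)+1: the distribution of a sum over all 2^n inclusion
# patterns of the doubled ranks, by exact integer convolution.
signed_rank_doubled_pmf <- function(d2) {
  total <- sum(d2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (d in d2) {
    shifted <- c(rep(0, d), counts[seq_len(total + 1 - d)])
    counts <- counts + shifted
  }
  counts / 2^length(d2)
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("<signed_rank> W+ = %g, n = %d, p = %.5g (%s, %s)\n",
              x$w_plus, x$n_effective, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Monte-Carlo power of the signed-rank cross-over test
#'
#' Estimates the power of a future cross-over study: each replicate draws
#' `n_subjects` between-arm contrasts from a normal law with the stated
#' effect mean and SD, applies [exact_wilcoxon_signed_rank()] at level
#' `alpha`, and power is the fraction of replicates rejecting. The
#' Monte-Carlo standard error `sqrt(power (1 - power) / n_sim)` is reported.
#'
#' @param effect_mean mean contrast under the alternative, (mg/dL)*min.
#' @param effect_sd between-subject SD of the contrast, (mg/dL)*min.
#' @param n_subjects planned sample size.
#' @param alpha one-sided significance level.
#' @param alternative direction of the test (default `"less"`: the product
#'   lowers the MTT response).
#' @param n_sim number of simulated trials (>= 1000).
#' @param seed integer seed.
#' @return An object of class `power_estimate`.
#' @export
power_by_simulation <- function(effect_mean, effect_sd, n_subjects,
                                alpha = 0.05, alternative = "less",
                                n_sim = 20000, seed = NULL) {
  stopifnot(n_sim >= 1000, effect_sd > 0, n_subjects >= 2)
  if (!is.null(seed)) set.seed(seed)
  reject <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    v <- rnorm(n_subjects, effect_mean, effect_sd)
    if (all(v == 0)) next
    p <- exact_wilcoxon_signed_rank(v, alternative = alternative)$p_value
    reject[i] <- p <= alpha
  }
  power <- mean(reject)
  structure(list(n_subjects = n_subjects, alpha = alpha,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 n_sim = n_sim, power = power,
                 mc_se = sqrt(power * (1 - power) / n_sim), seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> n = %d, alpha = %g: power %.3f (MC se %.4f, %d sims)\n",
              x$n_subjects, x$alpha, x$power, x$mc_se, x$n_sim))
  invisible(x)
}
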