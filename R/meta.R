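#' Read a table of double-checking trials
#'
#' Reads a CSV of two-arm trials of nurse double-checking of medicines
#' administration, with columns `label`, `events_checked`, `n_checked`,
#' `events_unchecked`, `n_unchecked` (error counts and administrations
#' with and without a double-check).
#'
#' @param path CSV path.
#' @return A validated data frame of class `trial_table`.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trial_table(df)
}

#' Validate a trial table
#'
#' @param df Data frame with columns `label`, `events_checked`,
#'   `n_checked`, `events_unchecked`, `n_unchecked`.
#' @return The data frame with class `trial_table` prepended.
#' @export
as_trial_table <- function(df) {
  required <- c("label", "events_checked", "n_checked",
                "events_unchecked", "n_unchecked")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("trial table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num <- df[required[-1]]
  if (any(num < 0) || any(df$n_checked <= 0) || any(df$n_unchecked <= 0) ||
      any(df$events_checked > df$n_checked) ||
      any(df$events_unchecked > df$n_unchecked)) {
    stop("trial counts must satisfy 0 <= events <= n with n > 0",
         call. = FALSE)
  }
  class(df) <- c("trial_table", class(df))
  df
}

#' DerSimonian-Laird random-effects meta-analysis of risk ratios
#'
#' Pools per-trial log risk ratios (checked vs unchecked) by
#' inverse-variance weighting with the DerSimonian-Laird moment estimate
#' of the between-trial variance tau-squared (floored at zero). A 0.5
#' continuity correction is added to all four cells of any trial with a
#' zero cell. The 95% confidence interval for the pooled mean uses
#' normal quantiles; the 95% prediction interval for the effect in a new
#' setting uses a t quantile with `k - 2` degrees of freedom and
#' variance `se^2 + tau^2`, so it widens materially with few trials and
#' any heterogeneity.
#'
#' @param trials A `trial_table` (see [read_trial_table()]) or a data
#'   frame with the same columns; at least two trials.
#' @return An object of class `re_result`: `pooled_log_rr`, `se_pooled`,
#'   `tau_squared`, `q_statistic`, `ci95` and `pi95` (both on the
#'   risk-ratio scale), `pi_reliable` (`FALSE` when `k = 2`), `k`.
#' @export
pool_random_effects <- function(trials) {
  if (!inherits(trials, "trial_table")) trials <- as_trial_table(trials)
  k <- nrow(trials)
  if (k < 2) stop("random-effects pooling requires at least 2 trials",
                  call. = FALSE)
  a <- trials$events_checked; n1 <- trials$n_checked
  c0 <- trials$events_unchecked; n0 <- trials$n_unchecked
  zero <- a == 0 | c0 == 0 | a == n1 | c0 == n0
  a[zero] <- a[zero] + 0.5; c0[zero] <- c0[zero] + 0.5
  n1[zero] <- n1[zero] + 1; n0[zero] <- n0[zero] + 1
  yi <- log((a / n1) / (c0 / n0))
  vi <- 1 / a - 1 / n1 + 1 / c0 - 1 / n0
  w <- 1 / vi
  pooled_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - pooled_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (vi + tau2)
  pooled <- sum(w_re * yi) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  ci <- exp(pooled + c(-1, 1) * stats::qnorm(0.975) * se)
  pi_reliable <- k >= 3
  pi <- if (pi_reliable) {
    exp(pooled + c(-1, 1) * stats::qt(0.975, df = k - 2) *
          sqrt(se^2 + tau2))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(pooled_log_rr = pooled, se_pooled = se,
                 tau_squared = tau2, q_statistic = q,
                 ci95 = ci, pi95 = pi, pi_reliable = pi_reliable, k = k,
                 yi = yi, vi = vi),
            class = "re_result")
}

#' @export
print.re_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis of %d trials\n", x$k))
  cat(sprintf("  pooled RR %.3f (95%% CI %.3f-%.3f), tau^2 = %.4f\n",
              exp(x$pooled_log_rr), x$ci95[1], x$ci95[2], x$tau_squared))
  if (x$pi_reliable) {
    cat(sprintf("  95%% prediction interval %.3f-%.3f\n",
                x$pi95[1], x$pi95[2]))
  } else {
    cat("  prediction interval unreliable with k = 2 trials\n")
  }
  invisible(x)
}

#' Convert a meta-analysis result to a lognormal input distribution
#'
#' Builds the node-2 input distribution from a pooled risk ratio and its
#' 95% prediction interval: lognormal with `mu = pooled_log_rr` and
#' `sigma = (log(upper) - log(lower)) / (2 * 1.96)`, truncated to
#' \[0, 1\] because the risk ratio is used directly as a probability.
#' The implied interval `exp(mu +/- 1.96 sigma)` reproduces a symmetric
#' (on the log scale) input interval. A degenerate interval collapses to
#' a deterministic spec.
#'
#' @param re_result A [pool_random_effects()] result with a finite
#'   prediction interval, or a list with `pooled_log_rr` and `pi95`.
#' @return A [dist_spec()].
#' @export
to_lognormal_spec <- function(re_result) {
  pi <- re_result$pi95
  if (anyNA(pi)) {
    stop("prediction interval unavailable (need at least 3 trials)",
         call. = FALSE)
  }
  if (any(pi <= 0)) stop("prediction interval bounds must be positive",
                         call. = FALSE)
  sigma <- (log(pi[2]) - log(pi[1])) / (2 * stats::qnorm(0.975))
  if (sigma == 0) {
    return(dist_spec("deterministic", min(exp(re_result$pooled_log_rr), 1)))
  }
  dist_spec("lognormal", c(re_result$pooled_log_rr, sigma),
            truncation = c(0, 1))
}
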