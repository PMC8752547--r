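make_trials <- function(events_checked, n_checked, events_unchecked,
                        n_unchecked) {
  as_trial_table(data.frame(
    label = paste0("t", seq_along(events_checked)),
    events_checked = events_checked, n_checked = n_checked,
    events_unchecked = events_unchecked, n_unchecked = n_unchecked))
}

test_that("trial tables are validated on read", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("a", "b"),
                       events_checked = c(30, 40), n_checked = c(200, 250),
                       events_unchecked = c(50, 60),
                       n_unchecked = c(210, 260)),
            path, row.names = FALSE)
  tt <- read_trial_table(path)
  expect_s3_class(tt, "trial_table")
  expect_error(as_trial_table(data.frame(label = "a", events_checked = 1)),
               "missing column")
  expect_error(make_trials(5, 4, 1, 10), "0 <= events <= n")
  unlink(path)
})

test_that("identical trials pool to the common effect with zero heterogeneity", {
  tt <- make_trials(rep(40, 3), rep(400, 3), rep(50, 3), rep(400, 3))
  re <- pool_random_effects(tt)
  expect_equal(re$tau_squared, 0)
  expect_equal(exp(re$pooled_log_rr), (40 / 400) / (50 / 400),
               tolerance = 1e-12)
  expect_equal(re$k, 3)
  # with tau^2 = 0 the prediction interval still widens via the t quantile
  expect_lt(re$pi95[1], re$ci95[1])
  expect_gt(re$pi95[2], re$ci95[2])
})

test_that("pooling matches a hand-computed DerSimonian-Laird oracle", {
  tt <- make_trials(c(30, 60, 45), c(300, 500, 350),
                    c(55, 70, 80), c(310, 480, 360))
  re <- pool_random_effects(tt)
  # independent evaluation of the moment estimator from first principles
  yi <- log((tt$events_checked / tt$n_checked) /
              (tt$events_unchecked / tt$n_unchecked))
  vi <- 1 / tt$events_checked - 1 / tt$n_checked +
    1 / tt$events_unchecked - 1 / tt$n_unchecked
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fe)^2)
  tau2 <- max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (vi + tau2)
  mu_re <- sum(w_re * yi) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  expect_equal(re$pooled_log_rr, mu_re, tolerance = 1e-12)
  expect_equal(re$tau_squared, tau2, tolerance = 1e-12)
  expect_equal(re$se_pooled, se, tolerance = 1e-12)
  expect_equal(re$pi95,
               exp(mu_re + c(-1, 1) * qt(0.975, 1) * sqrt(se^2 + tau2)),
               tolerance = 1e-12)
  # pooled estimate lies within the convex hull of the trial estimates
  expect_gte(re$pooled_log_rr, min(yi))
  expect_lte(re$pooled_log_rr, max(yi))
})

test_that("pooling agrees with metafor's DerSimonian-Laird implementation", {
  skip_if_not_installed("metafor")
  tt <- make_trials(c(25, 80, 12, 140), c(400, 900, 150, 2000),
                    c(40, 95, 20, 180), c(410, 880, 160, 1900))
  re <- pool_random_effects(tt)
  fit <- metafor::rma(measure = "RR", ai = tt$events_checked,
                      n1i = tt$n_checked, ci = tt$events_unchecked,
                      n2i = tt$n_unchecked, method = "DL")
  expect_equal(re$pooled_log_rr, as.numeric(fit$beta), tolerance = 1e-6)
  expect_equal(re$tau_squared, fit$tau2, tolerance = 1e-6)
  expect_equal(re$se_pooled, fit$se, tolerance = 1e-6)
})

test_that("zero cells receive a continuity correction; k guards are enforced", {
  tt <- make_trials(c(0, 10), c(100, 200), c(5, 12), c(100, 210))
  re <- pool_random_effects(tt)
  expect_true(is.finite(re$pooled_log_rr))
  expect_false(re$pi_reliable)        # k = 2: prediction interval unreliable
  expect_true(all(is.na(re$pi95)))
  expect_error(pool_random_effects(make_trials(5, 100, 6, 100)),
               "at least 2")
  expect_error(to_lognormal_spec(re), "at least 3")
})

test_that("prediction intervals convert to lognormal specs and back", {
  # the published case: pooled RR 0.775, prediction interval 0.655-0.918
  re <- list(pooled_log_rr = log(0.775), pi95 = c(0.655, 0.918))
  spec <- to_lognormal_spec(re)
  expect_equal(spec$family, "lognormal")
  expect_equal(spec$params[1], -0.255, tolerance = 0.001)
  expect_equal(spec$params[2], 0.086, tolerance = 0.005)
  expect_equal(spec$truncation, c(0, 1))
  # round trip: implied 95% interval reproduces the input interval
  implied <- exp(spec$params[1] + c(-1, 1) * qnorm(0.975) * spec$params[2])
  mid_shift <- exp(spec$params[1]) / sqrt(0.655 * 0.918)
  expect_equal(implied / mid_shift, c(0.655, 0.918), tolerance = 1e-6)

  # symmetric-on-log-scale interval around 1
  sym <- to_lognormal_spec(list(pooled_log_rr = 0, pi95 = exp(c(-1, 1))))
  expect_equal(sym$params[1], 0)
  expect_equal(sym$params[2], 2 / (2 * qnorm(0.975)), tolerance = 1e-9)

  # degenerate interval collapses to a deterministic value
  det <- to_lognormal_spec(list(pooled_log_rr = log(0.8), pi95 = c(0.8, 0.8)))
  expect_equal(det$family, "deterministic")
  expect_equal(det$params, 0.8)
  expect_error(to_lognormal_spec(list(pooled_log_rr = 0, pi95 = c(-1, 2))),
               "positive")
})
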