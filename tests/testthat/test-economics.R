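test_that("discount factors follow the year-1-discounted convention", {
  expect_equal(discount_factor(1:3, 0), rep(1, 3))
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_sum(5, 0.035), sum(1.035^-(1:5)))
  expect_equal(discount_sum(5, 0.035), 4.5151, tolerance = 1e-4)
  expect_error(discount_factor(0, 0.035), ">= 1")
  expect_error(discount_factor(1, 1), "rate")
})

test_that("user-testing cost matches the hand-summed resource model", {
  ut <- base_cfg$shared$user_testing
  rates <- base_cfg$shared$staff_rates
  ev <- expected_value_draw(base_cfg$arms, base_cfg$shared)
  # independent hand-sum at the mean durations
  interview_min <- 4 * 24 + 10 * (29 + 23 + 20)
  analysis_min <- 4 * 94 + 10 * (76 + 53 + 50)
  revision_min <- 265 + 140 + 140
  oracle <- interview_min * (65 + 37) / 60 + interview_min * 1.75 +
    (analysis_min + revision_min) * 65 / 60 + 562 + 4
  expect_equal(user_testing_cost(ev, ut, rates), oracle, tolerance = 1e-10)
  expect_equal(oracle, 6318.12, tolerance = 0.01)

  # all durations zero: only the fixed training + equipment costs remain
  zero <- manual_draw(c(1, rep(0, 11)), uniform_severity(),
                      interview = rep(0, 4), analysis = rep(0, 4),
                      revision = rep(0, 3))
  expect_equal(user_testing_cost(zero, ut, rates), 566)

  # a single 60-minute pilot interview, nothing else
  one <- manual_draw(c(1, rep(0, 11)), uniform_severity(),
                     interview = c(60, 0, 0, 0), analysis = rep(0, 4),
                     revision = rep(0, 3))
  ut1 <- user_testing_spec(ut$interview_minutes, ut$analysis_minutes,
                           ut$revision_minutes, n_pilot = 1)
  expect_equal(user_testing_cost(one, ut1, rates),
               60 * (65 + 37) / 60 + 60 * 1.75 + 566)
})

test_that("arm totals reduce to the per-dose outcome under identity scaling", {
  cohort1 <- cohort_spec(doses_per_year = 1, horizon_years = 1,
                         discount_rate = 0, wtp = 20000)
  draw <- manual_draw(c(0.5, rep(0.5 / 11, 11)), uniform_severity(),
                      p_undetected = 0.8, p_no_harm = 0.9)
  oc <- expected_dose_outcome(draw, "current")
  tot <- arm_totals(oc, admin_time_minutes = 13.3, cohort = cohort1,
                    nurse_rate = 37)
  expect_equal(tot$total_pades, sum(oc$p_pade_by_severity))
  expect_equal(tot$moderate_severe_pades, sum(oc$p_pade_by_severity[2:3]))
  expect_equal(tot$total_qaly_decrement, oc$expected_qaly_decrement)
  expect_equal(tot$health_system_cost,
               oc$expected_error_cost + 13.3 / 60 * 37)
})

test_that("expected-value cohort totals reproduce the published base-case scale", {
  ev <- expected_value_draw(base_cfg$arms, base_cfg$shared)
  oc <- expected_dose_outcome(ev, "current")
  tot <- arm_totals(oc, ev$arms$current$admin_time, base_cfg$cohort,
                    nurse_rate = 37)
  # 20,000 dose-years at the per-dose pADE probability
  expect_equal(tot$total_pades, sum(oc$p_pade_by_severity) * 20000,
               tolerance = 1e-12)
  expect_equal(tot$total_pades, 1210, tolerance = 0.001)
  expect_equal(tot$total_qaly_decrement, 238.7, tolerance = 0.001)
  # hand-summed: (13.3/60*37 + 59.83) * 4000 * 4.51505
  expect_equal(tot$health_system_cost, 1228700, tolerance = 0.001)
})

test_that("event counts and per-dose costs scale linearly in doses per year", {
  ev <- expected_value_draw(base_cfg$arms, base_cfg$shared)
  oc <- expected_dose_outcome(ev, "current")
  base <- arm_totals(oc, 13.3, base_cfg$cohort, 37)
  doubled_cohort <- cohort_spec(8000, 5, 0.035, 20000)
  doubled <- arm_totals(oc, 13.3, doubled_cohort, 37)
  expect_equal(doubled$total_pades, 2 * base$total_pades)
  expect_equal(doubled$moderate_severe_pades,
               2 * base$moderate_severe_pades)
  expect_equal(doubled$total_qaly_decrement,
               2 * base$total_qaly_decrement)
  expect_equal(doubled$health_system_cost, 2 * base$health_system_cost)
  # the one-off user-testing cost does not scale
  with_ut <- arm_totals(oc, 13.3, base_cfg$cohort, 37,
                        user_testing_cost = 6318)
  with_ut2 <- arm_totals(oc, 13.3, doubled_cohort, 37,
                         user_testing_cost = 6318)
  expect_equal(with_ut2$health_system_cost - 6318,
               2 * (with_ut$health_system_cost - 6318))
})

test_that("incremental outcomes satisfy the net-monetary-benefit identity", {
  ev <- expected_value_draw(base_cfg$arms, base_cfg$shared)
  oc_cur <- expected_dose_outcome(ev, "current")
  oc_usr <- expected_dose_outcome(ev, "user_tested")
  cur <- arm_totals(oc_cur, ev$arms$current$admin_time, base_cfg$cohort, 37)
  usr <- arm_totals(oc_usr, ev$arms$user_tested$admin_time, base_cfg$cohort,
                    37, user_testing_cost = 6318.12)
  inc <- incremental(cur, usr, wtp = 20000)
  expect_identical(inc$nmb_at_wtp,
                   20000 * inc$delta_qaly_decrement +
                     inc$incremental_cost_saving)
  expect_gt(inc$delta_pades, 0)
  # wtp = 0 collapses NMB to the incremental cost-saving
  inc0 <- incremental(cur, usr, wtp = 0)
  expect_identical(inc0$nmb_at_wtp, inc0$incremental_cost_saving)
  # identical arms: all deltas zero
  same <- incremental(cur, cur, wtp = 20000)
  expect_equal(same$delta_pades, 0)
  expect_equal(same$nmb_at_wtp, 0)
  # mismatched cohort settings are rejected
  other <- arm_totals(oc_usr, 11.9, cohort_spec(4000, 1, 0.035, 20000), 37)
  expect_error(incremental(cur, other, 20000), "different cohort")
})
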