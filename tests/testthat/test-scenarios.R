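test_that("an empty scenario leaves the configuration unchanged", {
  sc <- scenario_spec("noop")
  expect_equal(apply_scenario(base_cfg, sc), base_cfg)
})

test_that("cohort and distribution overrides are applied; unknown keys rejected", {
  sc <- scenario_spec("short", horizon_years = 1)
  cfg <- apply_scenario(base_cfg, sc)
  expect_equal(cfg$cohort$horizon_years, 1L)
  expect_equal(discount_sum(cfg$cohort$horizon_years,
                            cfg$cohort$discount_rate), 1 / 1.035)
  expect_equal(base_cfg$cohort$horizon_years, 5L)  # base untouched

  sc2 <- scenario_spec("harm", dist_overrides = list(
    p_no_harm = dist_spec("deterministic", 0.75)))
  cfg2 <- apply_scenario(base_cfg, sc2)
  expect_equal(cfg2$shared$p_no_harm$family, "deterministic")
  expect_equal(cfg2$shared$p_no_harm$params, 0.75)
  expect_equal(cfg2$shared$cost_pade, base_cfg$shared$cost_pade)

  sc3 <- scenario_spec("bad", dist_overrides = list(
    not_a_key = dist_spec("deterministic", 1)))
  expect_error(apply_scenario(base_cfg, sc3), "unknown override key")
  expect_error(scenario_spec("bad2", target_undetected_frequency = 1.2),
               "target_undetected_frequency")
  expect_error(scenario_spec("bad3", effectiveness_multiplier = 0),
               "effectiveness_multiplier")
})

test_that("doses override scales event counts exactly linearly at a fixed seed", {
  base_psa <- run_psa(base_cfg$arms, base_cfg$shared, base_cfg$cohort,
                      200, seed = 5)
  cfg5 <- apply_scenario(base_cfg, scenario_spec("x5", doses_per_year = 20000))
  psa5 <- run_psa(cfg5$arms, cfg5$shared, cfg5$cohort, 200, seed = 5)
  expect_equal(psa5$iterations$delta_pades,
               5 * base_psa$iterations$delta_pades, tolerance = 1e-12)
  expect_equal(psa5$iterations$delta_qaly,
               5 * base_psa$iterations$delta_qaly, tolerance = 1e-12)
  # ICS is affine: per-dose components scale, the one-off user-testing
  # cost (paid once, in the user arm) does not
  expect_equal(psa5$iterations$ics - 4 * psa5$iterations$user_testing_cost,
               5 * base_psa$iterations$ics, tolerance = 1e-9)
})

test_that("rescaling to the base-case frequency is the identity transform", {
  e_u <- dist_mean(base_cfg$shared$p_undetected)
  p_cur <- sum(base_cfg$arms$current$node1[-1]) /
    sum(base_cfg$arms$current$node1)
  arms <- rescale_error_frequency(base_cfg$arms, base_cfg$shared,
                                  target_undetected_frequency = p_cur * e_u,
                                  effectiveness_multiplier = 1)
  expect_equal(arms$current$node1, base_cfg$arms$current$node1,
               tolerance = 1e-12)
  expect_equal(arms$user_tested$severity, base_cfg$arms$user_tested$severity,
               tolerance = 1e-12)
})

test_that("the 32% rescale uses the expected uniform scale factor", {
  arms <- rescale_error_frequency(base_cfg$arms, base_cfg$shared, 0.32, 1)
  e_u <- dist_mean(base_cfg$shared$p_undetected)
  p_cur <- sum(base_cfg$arms$current$node1[-1]) /
    sum(base_cfg$arms$current$node1)
  k <- 0.32 / (p_cur * e_u)
  expect_equal(k, 0.507, tolerance = 0.001)
  expect_equal(unname(arms$current$severity),
               unname(base_cfg$arms$current$severity * k),
               tolerance = 1e-12)
  # the rescaled current arm hits the target expected frequency
  p_new <- sum(arms$current$node1[-1]) / sum(arms$current$node1)
  expect_equal(p_new * e_u, 0.32, tolerance = 1e-12)
})

test_that("rescaling preserves the relative reduction and severity composition", {
  freq <- function(arm) {
    sum(arm$node1[-1]) / sum(arm$node1) *
      dist_mean(base_cfg$shared$p_undetected)
  }
  base_ratio <- freq(base_cfg$arms$user_tested) / freq(base_cfg$arms$current)
  for (target in c(0.2, 0.32, 0.5)) {
    arms <- rescale_error_frequency(base_cfg$arms, base_cfg$shared, target, 1)
    expect_equal(freq(arms$user_tested) / freq(arms$current), base_ratio,
                 tolerance = 1e-12)
    for (lab in c("current", "user_tested")) {
      comp <- arms[[lab]]$severity / rowSums(arms[[lab]]$severity)
      comp0 <- base_cfg$arms[[lab]]$severity /
        rowSums(base_cfg$arms[[lab]]$severity)
      expect_equal(comp, comp0, tolerance = 1e-12)
    }
  }
  # halved effectiveness halves the relative reduction in expected frequency
  arms_h <- rescale_error_frequency(base_cfg$arms, base_cfg$shared, 0.32, 0.5)
  rel <- 1 - freq(arms_h$user_tested) / freq(arms_h$current)
  expect_equal(rel, (1 - base_ratio) / 2, tolerance = 1e-12)
  # unattainable targets are rejected
  expect_error(rescale_error_frequency(base_cfg$arms, base_cfg$shared,
                                       0.999, 1), "mass")
})

test_that("the built-in scenario suite runs and matches a direct base-case run", {
  scns <- built_in_scenarios()
  expect_true(all(c("base_case", "horizon_1yr", "horizon_10yr",
                    "doses_20000", "error_freq_32pct",
                    "error_freq_32pct_half_effect") %in% names(scns)))
  sub <- scns[c("base_case", "horizon_1yr")]
  tab <- run_scenario_suite(base_cfg, sub, n_samples = 300, seed = 11)
  expect_equal(nrow(tab), 2)
  direct <- run_psa(base_cfg$arms, base_cfg$shared, base_cfg$cohort,
                    300, seed = 11)
  expect_equal(tab$ics[1], direct$summary["ics", "mean"])
  expect_equal(tab$p_cost_effective[1], direct$p_cost_effective)
  # a shorter horizon shrinks the cost-saving
  expect_lt(tab$ics[2], tab$ics[1])
})
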