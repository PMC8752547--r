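#' Annual discount factor
#'
#' Discount factor `(1 + rate)^(-t)` for year `t = 1, ..., H`: the first
#' model year is discounted once. Event counts are never discounted; the
#' factor applies to costs and QALYs only. The one-off user-testing cost,
#' incurred at the start of the horizon, is not discounted either.
#'
#' @param year_index Integer year, `>= 1`.
#' @param rate Annual discount rate in `[0, 1)`.
#' @return Numeric discount factor(s).
#' @examples
#' discount_factor(1, 0.035)       # 0.96618
#' sum(discount_factor(1:5, 0.035))  # 4.5151
#' @export
discount_factor <- function(year_index, rate) {
  if (any(year_index < 1)) stop("year_index must be >= 1", call. = FALSE)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  (1 + rate)^(-year_index)
}

#' Sum of annual discount factors over a horizon
#'
#' @param horizon_years Integer horizon, `>= 1`.
#' @param rate Annual discount rate in `[0, 1)`.
#' @return `sum((1 + rate)^-(1:horizon_years))`.
#' @export
discount_sum <- function(horizon_years, rate) {
  sum(discount_factor(seq_len(horizon_years), rate))
}

#' Cost of the user-testing intervention
#'
#' Sums, for one joint draw (or vectorised across draws): interview time
#' costed at the combined pharmacist + nurse hourly rate plus
#' transcription at the per-spoken-minute rate; analysis time (per
#' interview) and guideline-revision time (per round) at the pharmacist
#' rate; and the fixed training and equipment costs. Incurred once at the
#' start of the horizon and therefore undiscounted.
#'
#' @param draws A `param_draws` object (any `n`).
#' @param user_testing A [user_testing_spec()] (interview counts, rates,
#'   fixed costs).
#' @param staff_rates Named numeric with `pharmacist` and `nurse` hourly
#'   rates (GBP/hour).
#' @return Numeric vector of length `draws$n`: intervention cost in GBP.
#' @export
user_testing_cost <- function(draws, user_testing, staff_rates) {
  stopifnot(inherits(draws, "param_draws"))
  ut <- draws$shared$ut
  counts <- c(user_testing$n_pilot, rep(user_testing$n_per_round, 3))
  interview_min <- as.numeric(ut$interview %*% counts)
  analysis_min <- as.numeric(ut$analysis %*% counts)
  revision_min <- rowSums(ut$revision)
  ph <- staff_rates[["pharmacist"]]
  nu <- staff_rates[["nurse"]]
  interview_min * (ph + nu) / 60 +
    interview_min * user_testing$transcription_rate +
    (analysis_min + revision_min) * ph / 60 +
    user_testing$training_cost + user_testing$equipment_cost
}

#' Cohort totals for one arm
#'
#' Scales per-dose tree outcomes to the cohort: expected event counts are
#' per-dose probabilities times `doses_per_year * horizon_years`
#' (undiscounted); costs and QALY decrements accrue annually and are
#' discounted with [discount_factor()]. The annual administration cost is
#' `admin_time/60 * nurse rate * doses_per_year`; the one-off
#' user-testing cost is added undiscounted when `user_testing_cost` is
#' supplied (the intervention arm).
#'
#' @param outcome A `dose_outcome` (per-dose expectations) or the
#'   equivalent vectorised list from the probabilistic engine.
#' @param admin_time_minutes Administration time per dose, minutes.
#' @param cohort A [cohort_spec()].
#' @param nurse_rate Nurse hourly cost, GBP/hour.
#' @param user_testing_cost Optional intervention cost (GBP) to add
#'   undiscounted; `NULL` for the comparator arm.
#' @return A list of class `arm_result` (vectorised over iterations):
#'   `total_pades`, `moderate_severe_pades` (undiscounted expected
#'   counts), `total_qaly_decrement` and `health_system_cost`
#'   (discounted).
#' @export
arm_totals <- function(outcome, admin_time_minutes, cohort, nurse_rate,
                       user_testing_cost = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  pade <- outcome[["p_pade"]]
  if (is.null(pade)) pade <- matrix(outcome[["p_pade_by_severity"]], nrow = 1)
  dsum <- discount_sum(cohort$horizon_years, cohort$discount_rate)
  doses_total <- cohort$doses_per_year * cohort$horizon_years
  annual_cost <- (admin_time_minutes / 60 * nurse_rate +
                    outcome$expected_error_cost) * cohort$doses_per_year
  annual_qaly <- outcome$expected_qaly_decrement * cohort$doses_per_year
  cost <- annual_cost * dsum
  if (!is.null(user_testing_cost)) cost <- cost + user_testing_cost
  structure(list(
    total_pades = rowSums(pade) * doses_total,
    moderate_severe_pades = rowSums(pade[, 2:3, drop = FALSE]) * doses_total,
    total_qaly_decrement = annual_qaly * dsum,
    health_system_cost = cost,
    cohort = cohort
  ), class = "arm_result")
}

#' Incremental outcomes (current minus user-tested)
#'
#' Differences are oriented so that positive values favour the
#' user-tested guidelines: fewer pADEs, fewer QALY decrements, an
#' incremental cost-saving (ICS). The net monetary benefit satisfies the
#' identity `nmb = wtp * delta_qaly_decrement + incremental_cost_saving`
#' exactly.
#'
#' @param current,user [arm_totals()] results computed on identical
#'   cohort settings.
#' @param wtp Willingness-to-pay per QALY, GBP.
#' @return A list of class `incremental_result` (vectorised):
#'   `delta_pades`, `delta_mod_severe_pades`, `delta_qaly_decrement`,
#'   `incremental_cost_saving`, `nmb_at_wtp`.
#' @export
incremental <- function(current, user, wtp) {
  stopifnot(inherits(current, "arm_result"), inherits(user, "arm_result"))
  if (!identical(unclass(current$cohort), unclass(user$cohort))) {
    stop("arms were computed on different cohort settings", call. = FALSE)
  }
  dq <- current$total_qaly_decrement - user$total_qaly_decrement
  ics <- current$health_system_cost - user$health_system_cost
  structure(list(
    delta_pades = current$total_pades - user$total_pades,
    delta_mod_severe_pades =
      current$moderate_severe_pades - user$moderate_severe_pades,
    delta_qaly_decrement = dq,
    incremental_cost_saving = ics,
    nmb_at_wtp = wtp * dq + ics
  ), class = "incremental_result")
}
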