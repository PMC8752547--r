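#' Define a sensitivity-analysis scenario
#'
#' A scenario is a named set of typed edits applied to a base
#' configuration: cohort overrides (`horizon_years`, `doses_per_year`),
#' replacement distributions for named shared inputs (e.g. a
#' deterministic `p_no_harm` of 0.75), and/or a structural rescaling of
#' the error frequency (see [rescale_error_frequency()]).
#'
#' @param name Scenario name.
#' @param horizon_years Optional replacement horizon.
#' @param doses_per_year Optional replacement annual dose count.
#' @param dist_overrides Named list of [dist_spec()]s replacing shared
#'   inputs; valid keys: `p_undetected`, `p_no_harm`, `cost_detected`,
#'   `cost_pade.minor|moderate|severe`,
#'   `qaly_decrement.minor|moderate|severe`.
#' @param target_undetected_frequency Optional target for the current
#'   arm's expected per-dose undetected-error frequency, in (0, 1).
#' @param effectiveness_multiplier Multiplier in (0, 1] on the relative
#'   reduction in undetected-error frequency achieved by user-testing
#'   (used with `target_undetected_frequency`; default 1).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, horizon_years = NULL, doses_per_year = NULL,
                          dist_overrides = list(),
                          target_undetected_frequency = NULL,
                          effectiveness_multiplier = 1) {
  if (!is.null(target_undetected_frequency) &&
      (target_undetected_frequency <= 0 || target_undetected_frequency >= 1)) {
    stop("target_undetected_frequency must be in (0, 1)", call. = FALSE)
  }
  if (effectiveness_multiplier <= 0 || effectiveness_multiplier > 1) {
    stop("effectiveness_multiplier must be in (0, 1]", call. = FALSE)
  }
  if (length(dist_overrides) &&
      (is.null(names(dist_overrides)) ||
       !all(vapply(dist_overrides, is_dist_spec, logical(1))))) {
    stop("dist_overrides must be a named list of dist_specs", call. = FALSE)
  }
  structure(list(name = name, horizon_years = horizon_years,
                 doses_per_year = doses_per_year,
                 dist_overrides = dist_overrides,
                 target_undetected_frequency = target_undetected_frequency,
                 effectiveness_multiplier = effectiveness_multiplier),
            class = "scenario_spec")
}

shared_override_keys <- function() {
  c("p_undetected", "p_no_harm", "cost_detected",
    paste0("cost_pade.", SEVERITY_LEVELS),
    paste0("qaly_decrement.", SEVERITY_LEVELS))
}

#' Apply a scenario to a configuration
#'
#' Returns a new configuration with the scenario's edits applied; the
#' base configuration is not modified. Unknown override keys raise an
#' error.
#'
#' @param base_config A configuration (see [base_case_config()]).
#' @param scenario A [scenario_spec()].
#' @return A new configuration list.
#' @export
apply_scenario <- function(base_config, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  cfg <- base_config
  if (!is.null(scenario$horizon_years) || !is.null(scenario$doses_per_year)) {
    co <- cfg$cohort
    cfg$cohort <- cohort_spec(
      doses_per_year = scenario$doses_per_year %||% co$doses_per_year,
      horizon_years = scenario$horizon_years %||% co$horizon_years,
      discount_rate = co$discount_rate, wtp = co$wtp)
  }
  for (key in names(scenario$dist_overrides)) {
    if (!key %in% shared_override_keys()) {
      stop(sprintf("unknown override key '%s' (valid: %s)", key,
                   paste(shared_override_keys(), collapse = ", ")),
           call. = FALSE)
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cfg$shared[[parts]] <- scenario$dist_overrides[[key]]
    } else {
      cfg$shared[[parts[1]]][[parts[2]]] <- scenario$dist_overrides[[key]]
    }
  }
  if (!is.null(scenario$target_undetected_frequency)) {
    cfg$arms <- rescale_error_frequency(
      cfg$arms, cfg$shared,
      target_undetected_frequency = scenario$target_undetected_frequency,
      effectiveness_multiplier = scenario$effectiveness_multiplier)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

arm_error_prob <- function(arm) sum(arm$node1[-1]) / sum(arm$node1)

rescale_arm <- function(arm, k) {
  if (k <= 0) stop("rescale factor must be > 0", call. = FALSE)
  total <- sum(arm$node1)
  sev <- arm$severity * k
  if (sum(sev) >= total) {
    stop("rescaling pushes the error probability mass to 1 or above",
         call. = FALSE)
  }
  node1 <- c(total - sum(sev), rowSums(sev))
  arm_spec(arm$label, node1, sev, arm$admin_time)
}

#' Rescale the expected undetected-error frequency
#'
#' Structural scenario for settings where errors are less frequent than
#' in the source clinical study (e.g. simpler, more familiar medicines).
#' The current arm's error-type pseudo-counts (node 1) and severity
#' pseudo-counts (node 4) are uniformly scaled by
#' `k = target / (p_error * E[p_undetected])` so that the expected
#' per-dose undetected-error frequency equals `target`; freed
#' probability mass moves to the no-error category. The user-tested arm
#' is scaled so that its relative reduction in undetected-error
#' frequency equals the base-case relative reduction times
#' `effectiveness_multiplier`. The conditional severity composition of
#' every error type is preserved exactly.
#'
#' @param arms List of the two [arm_spec()]s.
#' @param shared A [shared_spec()] (supplies `E[p_undetected]`).
#' @param target_undetected_frequency Target expected frequency in
#'   (0, 1).
#' @param effectiveness_multiplier Multiplier in (0, 1] on the relative
#'   reduction (1 = unchanged effectiveness).
#' @return A list of two rescaled [arm_spec()]s.
#' @export
rescale_error_frequency <- function(arms, shared,
                                    target_undetected_frequency,
                                    effectiveness_multiplier = 1) {
  if (target_undetected_frequency <= 0 || target_undetected_frequency >= 1) {
    stop("target_undetected_frequency must be in (0, 1)", call. = FALSE)
  }
  if (effectiveness_multiplier <= 0 || effectiveness_multiplier > 1) {
    stop("effectiveness_multiplier must be in (0, 1]", call. = FALSE)
  }
  e_undet <- dist_mean(shared$p_undetected)
  p_cur <- arm_error_prob(arms$current)
  p_usr <- arm_error_prob(arms$user_tested)
  rel_reduction <- 1 - p_usr / p_cur   # E[p_undetected] cancels
  k_cur <- target_undetected_frequency / (p_cur * e_undet)
  target_usr <- target_undetected_frequency *
    (1 - rel_reduction * effectiveness_multiplier)
  k_usr <- target_usr / (p_usr * e_undet)
  list(current = rescale_arm(arms$current, k_cur),
       user_tested = rescale_arm(arms$user_tested, k_usr))
}

#' Built-in sensitivity scenarios
#'
#' The package's standard scenario set: the base case; 1- and 10-year
#' horizons; 20,000 doses/year; deterministic detection probabilities at
#' the bounds of the meta-analytic 95% prediction interval (0.655,
#' 0.918); deterministic no-harm probabilities of 0.75 and 0.99; the
#' 32% undetected-error-frequency rescale; and the 32% rescale with the
#' relative effect of user-testing halved.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
built_in_scenarios <- function() {
  list(
    base_case = scenario_spec("base_case"),
    horizon_1yr = scenario_spec("horizon_1yr", horizon_years = 1),
    horizon_10yr = scenario_spec("horizon_10yr", horizon_years = 10),
    doses_20000 = scenario_spec("doses_20000", doses_per_year = 20000),
    detection_low = scenario_spec("detection_low", dist_overrides = list(
      p_undetected = dist_spec("deterministic", 0.655))),
    detection_high = scenario_spec("detection_high", dist_overrides = list(
      p_undetected = dist_spec("deterministic", 0.918))),
    no_harm_0.75 = scenario_spec("no_harm_0.75", dist_overrides = list(
      p_no_harm = dist_spec("deterministic", 0.75))),
    no_harm_0.99 = scenario_spec("no_harm_0.99", dist_overrides = list(
      p_no_harm = dist_spec("deterministic", 0.99))),
    error_freq_32pct = scenario_spec("error_freq_32pct",
      target_undetected_frequency = 0.32),
    error_freq_32pct_half_effect = scenario_spec(
      "error_freq_32pct_half_effect",
      target_undetected_frequency = 0.32, effectiveness_multiplier = 0.5)
  )
}

#' Run a suite of scenarios through the probabilistic engine
#'
#' Applies each scenario to the base configuration and runs a full
#' probabilistic analysis with the same seed, returning one summary row
#' per scenario.
#'
#' @param base_config A configuration (see [base_case_config()]).
#' @param scenarios Named list of [scenario_spec()]s (default
#'   [built_in_scenarios()]).
#' @param n_samples Iterations per scenario.
#' @param seed RNG seed (reused for every scenario).
#' @return A data frame with one row per scenario: mean reductions with
#'   credible intervals, incremental cost-saving, probability of
#'   cost-saving, net monetary benefit, probability of
#'   cost-effectiveness.
#' @export
run_scenario_suite <- function(base_config, scenarios = built_in_scenarios(),
                               n_samples = 20000L, seed = 1L) {
  rows <- lapply(scenarios, function(sc) {
    cfg <- apply_scenario(base_config, sc)
    psa <- run_psa(cfg$arms, cfg$shared, cfg$cohort, n_samples, seed)
    s <- psa$summary
    data.frame(
      scenario = sc$name,
      mod_severe_pades_avoided = s["delta_mod_severe", "mean"],
      mod_severe_lower = s["delta_mod_severe", "lower"],
      mod_severe_upper = s["delta_mod_severe", "upper"],
      pades_avoided = s["delta_pades", "mean"],
      pades_lower = s["delta_pades", "lower"],
      pades_upper = s["delta_pades", "upper"],
      qaly_decrements_avoided = s["delta_qaly", "mean"],
      qaly_lower = s["delta_qaly", "lower"],
      qaly_upper = s["delta_qaly", "upper"],
      ics = s["ics", "mean"],
      ics_lower = s["ics", "lower"],
      ics_upper = s["ics", "upper"],
      p_cost_saving = psa$p_cost_saving,
      nmb = s["nmb", "mean"],
      nmb_lower = s["nmb", "lower"],
      nmb_upper = s["nmb", "upper"],
      p_cost_effective = psa$p_cost_effective
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
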