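spec_to_list <- function(spec) {
  out <- list(family = spec$family, params = as.numeric(spec$params))
  if (!is.null(spec$truncation)) out$truncation <- as.numeric(spec$truncation)
  out
}

spec_from_list <- function(x, where) {
  if (is.null(x$family) || is.null(x$params)) {
    stop(sprintf("config field '%s': expected a distribution with 'family' and 'params'",
                 where), call. = FALSE)
  }
  tryCatch(
    dist_spec(x$family, unlist(x$params), truncation = unlist(x$truncation)),
    error = function(e) {
      stop(sprintf("config field '%s': %s", where, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

need <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop(sprintf("config is missing field '%s' under '%s'", field, where),
         call. = FALSE)
  }
  x[[field]]
}

#' Load a model configuration
#'
#' Reads a YAML (or JSON, by extension) configuration file describing the
#' two guideline arms, the shared inputs and the cohort settings, and
#' validates every type invariant (vector lengths, pseudo-count floors,
#' node-1 / severity-sum consistency, positive rates). The bundled
#' base-case file documents the schema.
#'
#' @param path Path to a configuration file.
#' @return A validated configuration list with elements `arms`, `shared`,
#'   `cohort` (see [base_case_config()]).
#' @seealso [write_config()] for the inverse; `write_config(load_config(p))`
#'   round-trips.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  arms_raw <- need(raw, "arms", "<top level>")
  arms <- lapply(c(current = "current", user_tested = "user_tested"),
    function(lab) {
      a <- need(arms_raw, lab, "arms")
      sev <- need(a, "severity", paste0("arms.", lab))
      sev <- do.call(rbind, lapply(sev, unlist))
      tryCatch(
        arm_spec(lab,
                 unlist(need(a, "node1_pseudo_counts", paste0("arms.", lab))),
                 sev,
                 spec_from_list(need(a, "admin_time", paste0("arms.", lab)),
                                paste0("arms.", lab, ".admin_time"))),
        error = function(e) {
          stop(sprintf("config arm '%s': %s", lab, conditionMessage(e)),
               call. = FALSE)
        }
      )
    })
  sh <- need(raw, "shared", "<top level>")
  sev_specs <- function(x, where) {
    lapply(stats::setNames(SEVERITY_LEVELS, SEVERITY_LEVELS), function(s) {
      spec_from_list(need(x, s, where), paste(where, s, sep = "."))
    })
  }
  ut_raw <- need(sh, "user_testing", "shared")
  specs_at <- function(x, keys, where) {
    lapply(keys, function(k) spec_from_list(need(x, k, where),
                                            paste(where, k, sep = ".")))
  }
  ut <- user_testing_spec(
    interview_minutes = specs_at(need(ut_raw, "interview_minutes", "user_testing"),
                                 c("pilot", "round1", "round2", "round3"),
                                 "user_testing.interview_minutes"),
    analysis_minutes = specs_at(need(ut_raw, "analysis_minutes", "user_testing"),
                                c("pilot", "round1", "round2", "round3"),
                                "user_testing.analysis_minutes"),
    revision_minutes = specs_at(need(ut_raw, "revision_minutes", "user_testing"),
                                c("round1", "round2", "round3"),
                                "user_testing.revision_minutes"),
    n_pilot = need(ut_raw, "n_pilot", "user_testing"),
    n_per_round = need(ut_raw, "n_per_round", "user_testing"),
    transcription_rate = need(ut_raw, "transcription_rate", "user_testing"),
    training_cost = need(ut_raw, "training_cost", "user_testing"),
    equipment_cost = need(ut_raw, "equipment_cost", "user_testing")
  )
  shared <- shared_spec(
    p_undetected = spec_from_list(need(sh, "p_undetected", "shared"),
                                  "shared.p_undetected"),
    p_no_harm = spec_from_list(need(sh, "p_no_harm", "shared"),
                               "shared.p_no_harm"),
    cost_detected = spec_from_list(need(sh, "cost_detected", "shared"),
                                   "shared.cost_detected"),
    cost_pade = sev_specs(need(sh, "cost_pade", "shared"), "shared.cost_pade"),
    qaly_decrement = sev_specs(need(sh, "qaly_decrement", "shared"),
                               "shared.qaly_decrement"),
    staff_rates = unlist(need(sh, "staff_rates", "shared")),
    user_testing = ut
  )
  co <- need(raw, "cohort", "<top level>")
  cohort <- cohort_spec(
    doses_per_year = need(co, "doses_per_year", "cohort"),
    horizon_years = need(co, "horizon_years", "cohort"),
    discount_rate = need(co, "discount_rate", "cohort"),
    wtp = need(co, "wtp", "cohort")
  )
  list(arms = arms, shared = shared, cohort = cohort)
}

#' Write a model configuration
#'
#' Serialises a configuration (as returned by [load_config()] or
#' [base_case_config()]) back to YAML or JSON so that
#' `load_config(write_config(cfg, p))` reproduces `cfg`.
#'
#' @param config A configuration list (`arms`, `shared`, `cohort`).
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  arm_to_list <- function(a) {
    list(node1_pseudo_counts = as.numeric(a$node1),
         severity = lapply(seq_len(nrow(a$severity)),
                           function(i) as.numeric(a$severity[i, ])),
         admin_time = spec_to_list(a$admin_time))
  }
  sh <- config$shared
  ut <- sh$user_testing
  named_specs <- function(specs, keys) {
    stats::setNames(lapply(specs, spec_to_list), keys)
  }
  raw <- list(
    arms = list(current = arm_to_list(config$arms$current),
                user_tested = arm_to_list(config$arms$user_tested)),
    shared = list(
      p_undetected = spec_to_list(sh$p_undetected),
      p_no_harm = spec_to_list(sh$p_no_harm),
      cost_detected = spec_to_list(sh$cost_detected),
      cost_pade = lapply(sh$cost_pade, spec_to_list),
      qaly_decrement = lapply(sh$qaly_decrement, spec_to_list),
      staff_rates = as.list(sh$staff_rates),
      user_testing = list(
        interview_minutes = named_specs(ut$interview_minutes,
                                        c("pilot", "round1", "round2", "round3")),
        analysis_minutes = named_specs(ut$analysis_minutes,
                                       c("pilot", "round1", "round2", "round3")),
        revision_minutes = named_specs(ut$revision_minutes,
                                       c("round1", "round2", "round3")),
        n_pilot = ut$n_pilot, n_per_round = ut$n_per_round,
        transcription_rate = ut$transcription_rate,
        training_cost = ut$training_cost,
        equipment_cost = ut$equipment_cost)
    ),
    cohort = list(doses_per_year = config$cohort$doses_per_year,
                  horizon_years = config$cohort$horizon_years,
                  discount_rate = config$cohort$discount_rate,
                  wtp = config$cohort$wtp)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}
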