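#' Run the full model and write its outputs
#'
#' End-to-end driver: loads (or accepts) a configuration, optionally
#' applies a named scenario, runs the probabilistic analysis, and writes
#' a summary JSON, the per-iteration table, the cost-effectiveness
#' acceptability curve, the cost-effectiveness plane and a reproducibility
#' manifest to `out_dir`. Every output is reproducible from the recorded
#' configuration, scenario, iteration count and seed.
#'
#' @param config A configuration list, or a path to a configuration file
#'   (see [load_config()]); defaults to the bundled base case.
#' @param scenario Optional scenario: a [scenario_spec()] or the name of
#'   a [built_in_scenarios()] entry.
#' @param n_samples Monte Carlo iterations.
#' @param seed RNG seed.
#' @param wtp Optional willingness-to-pay override (GBP/QALY).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `psa_result`, the output `paths`
#'   and the `manifest`.
#' @export
run_model <- function(config = NULL, scenario = NULL, n_samples = 20000L,
                      seed = 1L, wtp = NULL, out_dir = ".", quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  config_path <- NA_character_
  if (is.null(config)) {
    config_path <- base_case_path()
    config <- load_config(config_path)
  } else if (is.character(config)) {
    config_path <- config
    config <- load_config(config_path)
  }
  scenario_name <- "base_case"
  if (!is.null(scenario)) {
    if (is.character(scenario)) {
      builtin <- built_in_scenarios()
      if (!scenario %in% names(builtin)) {
        stop(sprintf("unknown scenario '%s' (built-in: %s)", scenario,
                     paste(names(builtin), collapse = ", ")), call. = FALSE)
      }
      scenario <- builtin[[scenario]]
    }
    if (!inherits(scenario, "scenario_spec")) {
      stop("scenario must be a scenario_spec or a built-in scenario name",
           call. = FALSE)
    }
    scenario_name <- scenario$name
    say("applying scenario '%s'", scenario_name)
    config <- apply_scenario(config, scenario)
  }
  if (!is.null(wtp)) {
    config$cohort <- cohort_spec(config$cohort$doses_per_year,
                                 config$cohort$horizon_years,
                                 config$cohort$discount_rate, wtp)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("running probabilistic analysis: %d iterations, seed %d",
      n_samples, seed)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  psa <- run_psa(config$arms, config$shared, config$cohort,
                 n_samples = n_samples, seed = seed)
  paths <- list(
    summary = file.path(out_dir, "summary.json"),
    iterations = file.path(out_dir, "iterations.csv"),
    ceac = file.path(out_dir, "ceac.csv"),
    ce_plane = file.path(out_dir, "ce_plane.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  say("writing outputs to %s", out_dir)
  utils::write.csv(psa$iterations, paths$iterations, row.names = FALSE)
  utils::write.csv(ceac(psa), paths$ceac, row.names = FALSE)
  plane <- ce_plane_export(psa, paths$ce_plane)
  s <- psa$summary
  tidy <- function(row) list(mean = s[row, "mean"],
                             cri_lower = s[row, "lower"],
                             cri_upper = s[row, "upper"])
  summary_out <- list(
    pades_avoided = tidy("delta_pades"),
    moderate_severe_pades_avoided = tidy("delta_mod_severe"),
    qaly_decrements_avoided = tidy("delta_qaly"),
    incremental_cost_saving = tidy("ics"),
    net_monetary_benefit = tidy("nmb"),
    user_testing_cost = tidy("user_testing_cost"),
    current_health_system_cost = tidy("cur_cost"),
    user_tested_health_system_cost = tidy("usr_cost"),
    p_cost_saving = psa$p_cost_saving,
    p_cost_effective = psa$p_cost_effective,
    dominant_quadrant_fraction = plane$dominant_quadrant_fraction,
    wtp = psa$wtp, n_samples = psa$n, seed = psa$seed)
  jsonlite::write_json(summary_out, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    config_path = config_path,
    config_md5 = if (!is.na(config_path))
      unname(tools::md5sum(config_path)) else NA,
    scenario = scenario_name,
    n_samples = n_samples, seed = seed, wtp = psa$wtp,
    package_version = as.character(utils::packageVersion("mederrcea")),
    outputs = lapply(paths[names(paths) != "manifest"], normalizePath,
                     mustWork = FALSE),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(psa = psa, paths = paths, manifest = manifest))
}
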