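#' Define a true generating model for simulation studies
#'
#' The ground truth from which synthetic clinical studies are drawn: per
#' arm, a 12-category error-type probability vector (no-error first) and
#' an 11 x 3 matrix of conditional severity probabilities, plus the
#' shared true detection / harm parameters and administration times used
#' by the end-to-end recovery check.
#'
#' @param arms List with elements `current` and `user_tested`, each a
#'   list with `node1_probs` (length 12, sums to 1), `severity_probs`
#'   (11 x 3, rows sum to 1) and `admin_time_mean` (minutes).
#' @param p_undetected,p_no_harm True shared probabilities.
#' @return Object of class `true_model`.
#' @export
true_model <- function(arms, p_undetected, p_no_harm) {
  for (lab in c("current", "user_tested")) {
    a <- arms[[lab]]
    if (is.null(a)) stop(sprintf("arms$%s missing", lab), call. = FALSE)
    if (length(a$node1_probs) != N_ERROR_TYPES + 1 ||
        abs(sum(a$node1_probs) - 1) > 1e-8 || any(a$node1_probs < 0)) {
      stop(sprintf("arms$%s$node1_probs must be a probability vector of length %d",
                   lab, N_ERROR_TYPES + 1), call. = FALSE)
    }
    sp <- as.matrix(a$severity_probs)
    if (!all(dim(sp) == c(N_ERROR_TYPES, 3)) || any(sp < 0) ||
        any(abs(rowSums(sp) - 1) > 1e-8)) {
      stop(sprintf("arms$%s$severity_probs must be %d x 3 with rows summing to 1",
                   lab, N_ERROR_TYPES), call. = FALSE)
    }
  }
  if (p_undetected < 0 || p_undetected > 1 || p_no_harm < 0 || p_no_harm > 1) {
    stop("true probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(arms = arms, p_undetected = p_undetected,
                 p_no_harm = p_no_harm),
            class = "true_model")
}

#' True model matching an existing configuration's expected values
#'
#' Convenience constructor: collapses every distribution of a model
#' configuration to its mean, giving the ground truth whose synthetic
#' studies should recover the configuration's probabilities.
#'
#' @param config A configuration (see [base_case_config()]).
#' @return A [true_model()].
#' @export
true_model_from_config <- function(config) {
  arm_truth <- function(arm) {
    list(node1_probs = as.numeric(arm$node1 / sum(arm$node1)),
         severity_probs = arm$severity / rowSums(arm$severity),
         admin_time_mean = dist_mean(arm$admin_time))
  }
  true_model(lapply(config$arms, arm_truth),
             p_undetected = dist_mean(config$shared$p_undetected),
             p_no_harm = dist_mean(config$shared$p_no_harm))
}

#' Simulate a clinical study of guideline use
#'
#' Emulates the structure of an in-situ study in which each participant
#' administers one dose and the outcome is classified into one of 34
#' joint cells: no error, or one of 11 error types at one of 3 potential
#' severity levels. Counts are a single multinomial draw over the joint
#' cells with probabilities `p_no_error` and
#' `p_type_i * p_severity_j_given_i`.
#'
#' @param model A [true_model()].
#' @param n_per_arm Participants per arm (0 allowed: all-zero counts, so
#'   posteriors reduce to the prior).
#' @return Named list (per arm) of lists with `no_error_count` (scalar)
#'   and `severity_counts` (11 x 3 matrix); counts sum to `n_per_arm`.
#' @export
simulate_clinical_study <- function(model, n_per_arm) {
  stopifnot(inherits(model, "true_model"), n_per_arm >= 0)
  lapply(model$arms, function(a) {
    sp <- as.matrix(a$severity_probs)
    cell_probs <- c(a$node1_probs[1],
                    as.numeric(t(a$node1_probs[-1] * sp)))
    counts <- if (n_per_arm == 0) rep(0, length(cell_probs)) else
      as.numeric(stats::rmultinom(1, n_per_arm, cell_probs))
    list(no_error_count = counts[1],
         severity_counts = matrix(counts[-1], nrow = N_ERROR_TYPES,
                                  byrow = TRUE,
                                  dimnames = list(
                                    paste0("type", seq_len(N_ERROR_TYPES)),
                                    SEVERITY_LEVELS)))
  })
}

#' Write simulated study counts to CSV
#'
#' One row per arm x cell (no-error plus 11 x 3 severity cells), in the
#' long format consumable by downstream posterior construction.
#'
#' @param study Output of [simulate_clinical_study()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_study_counts <- function(study, path) {
  rows <- lapply(names(study), function(lab) {
    s <- study[[lab]]
    long <- expand.grid(type = seq_len(N_ERROR_TYPES),
                        severity = SEVERITY_LEVELS)
    rbind(data.frame(arm = lab, type = 0L, severity = "none",
                     count = s$no_error_count),
          data.frame(arm = lab, type = long$type,
                     severity = as.character(long$severity),
                     count = s$severity_counts[cbind(long$type,
                                                     match(long$severity,
                                                           SEVERITY_LEVELS))]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Simulate two-arm double-checking trials
#'
#' Generates `k` trials for meta-analysis testing: each trial's log risk
#' ratio is drawn from `Normal(true_log_rr, tau^2)` (between-trial
#' heterogeneity), the unchecked arm's error risk is the trial's
#' baseline risk, and event counts are binomial in both arms.
#'
#' @param true_log_rr True mean log risk ratio (checked vs unchecked).
#' @param tau Between-trial standard deviation of the log risk ratio.
#' @param trial_sizes Data frame or list with `n_checked` and
#'   `n_unchecked` per trial (all >= 1).
#' @param baseline_risks Per-trial error risk without double-checking,
#'   each in (0, 1).
#' @return A `trial_table` data frame.
#' @export
simulate_double_check_trials <- function(true_log_rr, tau, trial_sizes,
                                         baseline_risks) {
  n1 <- trial_sizes$n_checked; n0 <- trial_sizes$n_unchecked
  k <- length(baseline_risks)
  stopifnot(length(n1) == k, length(n0) == k, all(n1 >= 1), all(n0 >= 1),
            tau >= 0)
  if (any(baseline_risks <= 0) || any(baseline_risks >= 1)) {
    stop("baseline_risks must lie in (0, 1)", call. = FALSE)
  }
  theta <- stats::rnorm(k, true_log_rr, tau)
  risk_checked <- baseline_risks * exp(theta)
  if (any(risk_checked > 1)) {
    stop("baseline risk times the trial risk ratio exceeds 1", call. = FALSE)
  }
  as_trial_table(data.frame(
    label = paste0("trial", seq_len(k)),
    events_checked = stats::rbinom(k, n1, risk_checked),
    n_checked = n1,
    events_unchecked = stats::rbinom(k, n0, baseline_risks),
    n_unchecked = n0
  ))
}

#' End-to-end parameter-recovery check
#'
#' Simulates a clinical study from a true model, builds Dirichlet
#' posteriors from the simulated counts, runs the full probabilistic
#' analysis, and compares the Monte Carlo mean outcomes with the
#' closed-form outcomes of the true model evaluated at its exact
#' parameter values ([expected_value_draw()] route). As `n_per_arm` and
#' `psa_n` grow, the two converge.
#'
#' @param model A [true_model()].
#' @param shared A [shared_spec()] supplying costs, QALY decrements and
#'   the user-testing model (its `p_undetected` / `p_no_harm` are
#'   replaced by the true model's deterministic values for the
#'   closed-form reference).
#' @param cohort A [cohort_spec()].
#' @param n_per_arm Simulated participants per arm.
#' @param psa_n Monte Carlo iterations.
#' @param seed RNG seed.
#' @return A list: `psa_means` (Monte Carlo means of the incremental
#'   outcomes), `closed_form` (true-model expected values),
#'   `abs_difference`, and the simulated `study`.
#' @export
end_to_end_recovery <- function(model, shared, cohort, n_per_arm = 1e5,
                                psa_n = 2000, seed = 1L) {
  stopifnot(inherits(model, "true_model"))
  set.seed(seed)
  study <- simulate_clinical_study(model, n_per_arm)
  arms <- list(
    current = arm_spec_from_counts(
      study$current$no_error_count, study$current$severity_counts,
      dist_spec("deterministic", model$arms$current$admin_time_mean),
      label = "current"),
    user_tested = arm_spec_from_counts(
      study$user_tested$no_error_count, study$user_tested$severity_counts,
      dist_spec("deterministic", model$arms$user_tested$admin_time_mean),
      label = "user_tested"))
  shared_det <- shared
  shared_det$p_undetected <- dist_spec("deterministic", model$p_undetected)
  shared_det$p_no_harm <- dist_spec("deterministic", model$p_no_harm)
  psa <- run_psa(arms, shared_det, cohort, n_samples = psa_n, seed = seed)
  closed <- closed_form_expected(model, shared_det, cohort)
  psa_means <- psa$summary[c("delta_pades", "delta_mod_severe",
                             "delta_qaly", "ics", "nmb"), "mean"]
  list(psa_means = psa_means, closed_form = closed,
       abs_difference = abs(psa_means - closed[names(psa_means)]),
       study = study, psa = psa)
}

# Closed-form expected incremental outcomes of a true model: evaluates
# the tree and cohort economics at the exact true parameter values, with
# every cost/QALY/user-testing input at its distribution mean.
closed_form_expected <- function(model, shared, cohort) {
  arm_from_truth <- function(a, lab) {
    # scale true probabilities to pseudo-counts; only the proportions
    # matter for an expected-value evaluation
    sev <- a$node1_probs[-1] * as.matrix(a$severity_probs) * 1e6 + 1e-9
    arm_spec(lab, c(a$node1_probs[1] * 1e6 + 1e-9, rowSums(sev)), sev,
             dist_spec("deterministic", a$admin_time_mean))
  }
  arms <- list(
    current = arm_from_truth(model$arms$current, "current"),
    user_tested = arm_from_truth(model$arms$user_tested, "user_tested"))
  ev <- expected_value_draw(arms, shared)
  nurse <- shared$staff_rates[["nurse"]]
  ut_cost <- user_testing_cost(ev, shared$user_testing, shared$staff_rates)
  out_cur <- tree_outcomes_vec(ev, "current")
  out_usr <- tree_outcomes_vec(ev, "user_tested")
  cur <- arm_totals(out_cur, out_cur$admin_time, cohort, nurse)
  usr <- arm_totals(out_usr, out_usr$admin_time, cohort, nurse,
                    user_testing_cost = ut_cost)
  inc <- incremental(cur, usr, cohort$wtp)
  c(delta_pades = inc$delta_pades,
    delta_mod_severe = inc$delta_mod_severe_pades,
    delta_qaly = inc$delta_qaly_decrement,
    ics = inc$incremental_cost_saving,
    nmb = inc$nmb_at_wtp)
}
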