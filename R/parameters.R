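#' @keywords internal
"_PACKAGE"

N_ERROR_TYPES <- 11L
SEVERITY_LEVELS <- c("minor", "moderate", "severe")

#' Guideline-arm specification
#'
#' Holds one arm's Dirichlet pseudo-counts for the per-dose error-type
#' multinomial (the "no error" category followed by the 11 error types),
#' the per-type severity pseudo-counts conditional on a harmful undetected
#' error, and the administration-time distribution in minutes per dose.
#'
#' The node-1 vector is stored redundantly with the severity matrix and
#' cross-validated: each error type's node-1 pseudo-count must equal the
#' sum of its three severity pseudo-counts, reflecting the joint
#' type-by-severity cell counts (plus a 0.1 prior per cell) from which
#' both are built. Pseudo-counts may be fractional: ties in severity
#' assignment of observed errors produce half-counts.
#'
#' @param label `"current"` or `"user_tested"`.
#' @param node1_pseudo_counts Numeric length 12: no-error then error types
#'   1-11; all > 0 (posteriors built with the default prior sit at or
#'   above the 0.1 prior floor).
#' @param severity 11 x 3 numeric matrix of pseudo-counts (rows = error
#'   types, columns = minor/moderate/severe); all entries > 0 and each
#'   row must sum to the matching node-1 entry.
#' @param admin_time [dist_spec()] for administration time, minutes/dose.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(label = c("current", "user_tested"),
                     node1_pseudo_counts, severity, admin_time) {
  label <- match.arg(label)
  node1 <- as.numeric(node1_pseudo_counts)
  if (length(node1) != N_ERROR_TYPES + 1L) {
    stop(sprintf("node1_pseudo_counts must have length %d (no-error then %d error types), got %d",
                 N_ERROR_TYPES + 1L, N_ERROR_TYPES, length(node1)),
         call. = FALSE)
  }
  if (any(node1 <= 0)) {
    stop("node-1 pseudo-counts must all be > 0", call. = FALSE)
  }
  severity <- as.matrix(severity)
  if (!all(dim(severity) == c(N_ERROR_TYPES, 3L))) {
    stop(sprintf("severity must be a %d x 3 matrix", N_ERROR_TYPES),
         call. = FALSE)
  }
  if (any(severity <= 0)) {
    stop("severity pseudo-counts must all be > 0", call. = FALSE)
  }
  if (any(abs(rowSums(severity) - node1[-1]) > 1e-8)) {
    bad <- which(abs(rowSums(severity) - node1[-1]) > 1e-8)
    stop(sprintf("severity rows must sum to the node-1 entry for each error type (mismatch at type %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is_dist_spec(admin_time)) {
    stop("admin_time must be a dist_spec", call. = FALSE)
  }
  dimnames(severity) <- list(paste0("type", seq_len(N_ERROR_TYPES)),
                             SEVERITY_LEVELS)
  names(node1) <- c("no_error", rownames(severity))
  structure(list(label = label, node1 = node1, severity = severity,
                 admin_time = admin_time),
            class = "arm_spec")
}

#' Shared (arm-independent) model inputs
#'
#' Inputs common to both guideline arms: the probability an error remains
#' undetected before administration (node 2; a double-checking risk ratio
#' used directly as a probability, hence truncated at 1), the probability
#' an undetected error causes no harm (node 3), unit costs, QALY
#' decrements by harm severity, staff rates, and the user-testing
#' resource model.
#'
#' @param p_undetected [dist_spec()], node 2.
#' @param p_no_harm [dist_spec()], node 3.
#' @param cost_detected [dist_spec()], cost (GBP) of correcting an error
#'   detected before administration.
#' @param cost_pade Named list of three [dist_spec()]s
#'   (minor/moderate/severe treatment cost, GBP).
#' @param qaly_decrement Named list of three [dist_spec()]s
#'   (minor/moderate/severe QALY decrement).
#' @param staff_rates Named numeric: `pharmacist` and `nurse` hourly cost
#'   (GBP/hour), both > 0.
#' @param user_testing A [user_testing_spec()].
#' @return An object of class `shared_spec`.
#' @export
shared_spec <- function(p_undetected, p_no_harm, cost_detected, cost_pade,
                        qaly_decrement, staff_rates, user_testing) {
  check_sev_list <- function(x, what) {
    if (!is.list(x) || length(x) != 3 ||
        !setequal(names(x), SEVERITY_LEVELS) ||
        !all(vapply(x, is_dist_spec, logical(1)))) {
      stop(sprintf("%s must be a named list of three dist_specs (minor, moderate, severe)",
                   what), call. = FALSE)
    }
    x[SEVERITY_LEVELS]
  }
  stopifnot(is_dist_spec(p_undetected), is_dist_spec(p_no_harm),
            is_dist_spec(cost_detected))
  cost_pade <- check_sev_list(cost_pade, "cost_pade")
  qaly_decrement <- check_sev_list(qaly_decrement, "qaly_decrement")
  staff_rates <- unlist(staff_rates)[c("pharmacist", "nurse")]
  if (anyNA(staff_rates) || any(staff_rates <= 0)) {
    stop("staff_rates must provide positive 'pharmacist' and 'nurse' hourly rates",
         call. = FALSE)
  }
  if (!inherits(user_testing, "user_testing_spec")) {
    stop("user_testing must be a user_testing_spec", call. = FALSE)
  }
  structure(list(p_undetected = p_undetected, p_no_harm = p_no_harm,
                 cost_detected = cost_detected, cost_pade = cost_pade,
                 qaly_decrement = qaly_decrement, staff_rates = staff_rates,
                 user_testing = user_testing),
            class = "shared_spec")
}

#' User-testing resource model
#'
#' Resource use of the one-off user-testing intervention: a pilot round
#' of interviews followed by three iterative rounds, each interview
#' attended by a pharmacist (user-tester) and a nurse (participant),
#' transcribed at a per-spoken-minute rate and analysed by the
#' pharmacist; each post-pilot round is followed by a guideline revision
#' by the pharmacist; plus fixed training and equipment costs.
#'
#' @param interview_minutes List of 4 [dist_spec()]s: pilot then rounds
#'   1-3, minutes per interview.
#' @param analysis_minutes List of 4 [dist_spec()]s: minutes of analysis
#'   per interview, pilot then rounds 1-3.
#' @param revision_minutes List of 3 [dist_spec()]s: minutes to revise
#'   the guideline after rounds 1-3.
#' @param n_pilot Number of pilot interviews (default 4).
#' @param n_per_round Number of interviews in each of rounds 1-3
#'   (default 10).
#' @param transcription_rate GBP per spoken minute (default 1.75).
#' @param training_cost One-off user-tester training cost, GBP
#'   (default 562).
#' @param equipment_cost One-off equipment cost, GBP (default 4).
#' @return An object of class `user_testing_spec`.
#' @export
user_testing_spec <- function(interview_minutes, analysis_minutes,
                              revision_minutes, n_pilot = 4L,
                              n_per_round = 10L, transcription_rate = 1.75,
                              training_cost = 562, equipment_cost = 4) {
  check_list <- function(x, len, what) {
    if (!is.list(x) || length(x) != len ||
        !all(vapply(x, is_dist_spec, logical(1)))) {
      stop(sprintf("%s must be a list of %d dist_specs", what, len),
           call. = FALSE)
    }
    x
  }
  interview_minutes <- check_list(interview_minutes, 4, "interview_minutes")
  analysis_minutes <- check_list(analysis_minutes, 4, "analysis_minutes")
  revision_minutes <- check_list(revision_minutes, 3, "revision_minutes")
  n_pilot <- as.integer(n_pilot); n_per_round <- as.integer(n_per_round)
  if (is.na(n_pilot) || n_pilot < 1 || is.na(n_per_round) || n_per_round < 1) {
    stop("interview counts must be positive integers", call. = FALSE)
  }
  if (transcription_rate < 0 || training_cost < 0 || equipment_cost < 0) {
    stop("rates and fixed costs must be >= 0", call. = FALSE)
  }
  structure(list(interview_minutes = interview_minutes,
                 analysis_minutes = analysis_minutes,
                 revision_minutes = revision_minutes,
                 n_pilot = n_pilot, n_per_round = n_per_round,
                 transcription_rate = transcription_rate,
                 training_cost = training_cost,
                 equipment_cost = equipment_cost),
            class = "user_testing_spec")
}

#' Cohort and decision settings
#'
#' @param doses_per_year Doses administered per year across the cohort
#'   (base case 4000).
#' @param horizon_years Time horizon in whole years (base case 5).
#' @param discount_rate Annual discount rate for costs and QALYs
#'   (base case 0.035).
#' @param wtp Willingness-to-pay per QALY, GBP (base case 20000).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(doses_per_year = 4000, horizon_years = 5L,
                        discount_rate = 0.035, wtp = 20000) {
  horizon_years <- as.integer(horizon_years)
  doses_per_year <- as.numeric(doses_per_year)
  discount_rate <- as.numeric(discount_rate)
  wtp <- as.numeric(wtp)
  if (doses_per_year <= 0) stop("doses_per_year must be > 0", call. = FALSE)
  if (is.na(horizon_years) || horizon_years < 1) {
    stop("horizon_years must be an integer >= 1", call. = FALSE)
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount_rate must be in [0, 1)", call. = FALSE)
  }
  if (wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  structure(list(doses_per_year = doses_per_year,
                 horizon_years = horizon_years,
                 discount_rate = discount_rate, wtp = wtp),
            class = "cohort_spec")
}

#' Dirichlet posterior from observed counts
#'
#' Conjugate Bayesian update of a Dirichlet prior with a small pseudo-count
#' per cell (default 0.1) by observed multinomial counts. The small prior
#' guarantees a low but non-zero posterior probability for events too rare
#' to appear in a modest study. Observed counts may be fractional: when an
#' observed error is tied between two severity levels, half a count goes
#' to each.
#'
#' @param observed_counts Non-negative numeric vector of observed counts
#'   per category.
#' @param prior_count Positive pseudo-count added to every cell
#'   (default 0.1).
#' @return A `dirichlet` [dist_spec()] with pseudo-counts
#'   `observed_counts + prior_count`.
#' @examples
#' # severity cells observed as (5.0, 5.5, 0.0): posterior (5.1, 5.6, 0.1)
#' build_dirichlet_posterior(c(5.0, 5.5, 0.0))
#' @export
build_dirichlet_posterior <- function(observed_counts, prior_count = 0.1) {
  observed_counts <- as.numeric(observed_counts)
  if (anyNA(observed_counts) || any(observed_counts < 0)) {
    stop("observed_counts must be non-negative", call. = FALSE)
  }
  if (length(prior_count) != 1 || is.na(prior_count) || prior_count <= 0) {
    stop("prior_count must be a positive scalar", call. = FALSE)
  }
  dist_spec("dirichlet", observed_counts + prior_count)
}

#' Build an arm specification from joint study counts
#'
#' Converts observed clinical-study counts — a no-error count plus an
#' 11 x 3 error-type-by-severity count matrix — into an [arm_spec()] by
#' conjugate updating with a 0.1 prior per joint cell. Each error type's
#' node-1 pseudo-count is the sum of its three posterior severity cells;
#' the no-error category receives a prior of `3 * prior_count` so that it
#' sits on the same prior scale as an error type (whose three severity
#' cells contribute that much jointly).
#'
#' @param no_error_count Observed doses with no error.
#' @param severity_counts 11 x 3 matrix of observed counts (fractional
#'   allowed).
#' @param admin_time [dist_spec()] for the arm's administration time.
#' @param label Arm label.
#' @param prior_count Prior pseudo-count per severity cell (default 0.1).
#' @return An [arm_spec()].
#' @export
arm_spec_from_counts <- function(no_error_count, severity_counts, admin_time,
                                 label = c("current", "user_tested"),
                                 prior_count = 0.1) {
  label <- match.arg(label)
  severity_counts <- as.matrix(severity_counts)
  if (!all(dim(severity_counts) == c(N_ERROR_TYPES, 3L))) {
    stop(sprintf("severity_counts must be %d x 3", N_ERROR_TYPES),
         call. = FALSE)
  }
  if (any(severity_counts < 0) || no_error_count < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  sev_post <- severity_counts + prior_count
  node1 <- c(no_error_count + 3 * prior_count, rowSums(sev_post))
  arm_spec(label, node1, sev_post, admin_time)
}

base_case_path <- function() {
  system.file("extdata", "base_case.yaml", package = "mederrcea",
              mustWork = TRUE)
}

#' The bundled base-case configuration
#'
#' Loads the base-case model configuration shipped with the package:
#' Dirichlet error-type and severity pseudo-counts for both guideline
#' arms, the shared detection / harm / cost / QALY distributions, staff
#' rates, the user-testing resource model, and the cohort settings
#' (4000 doses/year, 5 years, 3.5% discounting, GBP 20,000/QALY).
#'
#' @return A model configuration: list with elements `arms` (list of two
#'   [arm_spec()]s named `current` and `user_tested`), `shared`
#'   ([shared_spec()]) and `cohort` ([cohort_spec()]).
#' @export
base_case_config <- function() {
  load_config(base_case_path())
}
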