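#' Enumerate every terminal path of the per-dose decision tree
#'
#' The tree has four chance nodes per dose: (1) which of 11 error types
#' occurs, if any; (2) whether an error remains undetected before
#' administration (a double-check by a second nurse being the only
#' detection opportunity); (3) whether an undetected error causes harm;
#' (4) the severity of harm (minor / moderate / severe). This yields 56
#' terminal paths: one no-error path plus, for each error type, a
#' detected path, an undetected-no-harm path, and three severity paths.
#'
#' Detected errors carry only the correction cost; undetected harmless
#' errors carry neither cost nor QALY decrement; preventable adverse drug
#' events (pADEs) carry the severity-specific treatment cost and QALY
#' decrement. Administration-time costs are handled at the cohort stage,
#' not here.
#'
#' @param draw A single-iteration `param_draws` object (see
#'   [sample_draw()] or [draw_slice()]).
#' @param arm `"current"` or `"user_tested"`.
#' @return A 56-row data frame with columns `path`, `probability`,
#'   `cost`, `qaly_decrement`. Probabilities sum to 1.
#' @export
enumerate_paths <- function(draw, arm = c("current", "user_tested")) {
  arm <- match.arg(arm)
  stopifnot(inherits(draw, "param_draws"), draw$n == 1)
  a <- draw$arms[[arm]]
  sh <- draw$shared
  p1 <- as.numeric(a$node1)
  u <- sh$p_undetected
  h <- sh$p_no_harm
  cost_pade <- as.numeric(sh$cost_pade)
  qaly <- as.numeric(sh$qaly_decrement)

  rows <- vector("list", 1 + N_ERROR_TYPES * 5)
  rows[[1]] <- data.frame(path = "no_error", probability = p1[1],
                          cost = 0, qaly_decrement = 0)
  k <- 2L
  for (i in seq_len(N_ERROR_TYPES)) {
    pe <- p1[i + 1]
    sev <- as.numeric(a$severity[[i]])
    rows[[k]] <- data.frame(
      path = sprintf("type%02d:detected", i),
      probability = pe * (1 - u), cost = sh$cost_detected,
      qaly_decrement = 0)
    rows[[k + 1L]] <- data.frame(
      path = sprintf("type%02d:undetected:no_harm", i),
      probability = pe * u * h, cost = 0, qaly_decrement = 0)
    for (j in 1:3) {
      rows[[k + 1L + j]] <- data.frame(
        path = sprintf("type%02d:undetected:pade_%s", i, SEVERITY_LEVELS[j]),
        probability = pe * u * (1 - h) * sev[j],
        cost = cost_pade[j], qaly_decrement = qaly[j])
    }
    k <- k + 5L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-dose expected outcome for one arm and one draw
#'
#' Aggregates [enumerate_paths()]: outcome-class probabilities, and the
#' probability-weighted expected error-related cost and QALY decrement
#' per dose. Severity-specific pADE probabilities combine each error
#' type's conditional severity split (node 4) weighted by its node-1
#' probability.
#'
#' @inheritParams enumerate_paths
#' @return A list of class `dose_outcome`: `p_no_error`,
#'   `p_detected_error`, `p_undetected_no_harm`, `p_pade_by_severity`
#'   (named length-3), `expected_error_cost`, `expected_qaly_decrement`.
#'   The four probability components sum to 1.
#' @export
expected_dose_outcome <- function(draw, arm = c("current", "user_tested")) {
  arm <- match.arg(arm)
  paths <- enumerate_paths(draw, arm)
  pade <- vapply(SEVERITY_LEVELS, function(s) {
    sum(paths$probability[grepl(paste0("pade_", s, "$"), paths$path)])
  }, numeric(1))
  structure(list(
    p_no_error = paths$probability[paths$path == "no_error"],
    p_detected_error = sum(paths$probability[grepl(":detected$", paths$path)]),
    p_undetected_no_harm = sum(paths$probability[grepl(":no_harm$", paths$path)]),
    p_pade_by_severity = pade,
    expected_error_cost = sum(paths$probability * paths$cost),
    expected_qaly_decrement = sum(paths$probability * paths$qaly_decrement)
  ), class = "dose_outcome")
}

# Vectorised tree evaluation over all iterations of a param_draws object.
# Same arithmetic as enumerate_paths()/expected_dose_outcome(), one row
# per iteration; the per-draw route is the audit oracle for this one.
tree_outcomes_vec <- function(draws, arm) {
  a <- draws$arms[[arm]]
  sh <- draws$shared
  n <- draws$n
  p_err <- a$node1[, -1, drop = FALSE]              # n x 11
  p_err_total <- rowSums(p_err)
  u <- sh$p_undetected
  h <- sh$p_no_harm
  # pade_sev[, j] = sum_i p_err[, i] * severity_i[, j] * u * (1 - h)
  sev_mix <- matrix(0, n, 3)
  for (i in seq_len(N_ERROR_TYPES)) {
    sev_mix <- sev_mix + p_err[, i] * a$severity[[i]]
  }
  pade <- (u * (1 - h)) * sev_mix
  p_detected <- p_err_total * (1 - u)
  cost <- p_detected * sh$cost_detected + rowSums(pade * sh$cost_pade)
  qaly <- rowSums(pade * sh$qaly_decrement)
  list(p_no_error = a$node1[, 1],
       p_detected_error = p_detected,
       p_undetected_no_harm = p_err_total * u * h,
       p_pade = pade,
       expected_error_cost = cost,
       expected_qaly_decrement = qaly,
       admin_time = a$admin_time)
}
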