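cri <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

summarise_column <- function(x) {
  q <- cri(x)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_samples` joint parameter realisations ([sample_draws()]),
#' pushes each through the per-dose decision tree and the cohort
#' economics for both guideline arms, and summarises the incremental
#' outcomes. Shared parameters use common random numbers across arms;
#' arm-specific Dirichlets and administration times are independent.
#' Credible intervals are empirical 2.5/97.5 percentiles (linear
#' interpolation). The run is fully reproducible from `seed`.
#'
#' @param arms List of two [arm_spec()]s (`current`, `user_tested`).
#' @param shared A [shared_spec()].
#' @param cohort A [cohort_spec()].
#' @param n_samples Number of Monte Carlo iterations (default 20000,
#'   sufficient for convergence of errors, costs and net monetary
#'   benefit at the base-case inputs).
#' @param seed Integer RNG seed.
#' @return An object of class `psa_result`: `iterations` (data frame,
#'   one row per draw), `summary` (matrix of mean / 2.5% / 97.5% per
#'   outcome), `p_cost_saving`, `p_cost_effective` (at the cohort's
#'   willingness-to-pay), `wtp`, `n`, `seed`, `cohort`.
#' @export
run_psa <- function(arms, shared, cohort, n_samples = 20000L, seed = 1L) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  draws <- sample_draws(arms, shared, n_samples)
  ut_cost <- user_testing_cost(draws, shared$user_testing,
                               shared$staff_rates)
  out_cur <- tree_outcomes_vec(draws, "current")
  out_usr <- tree_outcomes_vec(draws, "user_tested")
  nurse <- shared$staff_rates[["nurse"]]
  cur <- arm_totals(out_cur, out_cur$admin_time, cohort, nurse)
  usr <- arm_totals(out_usr, out_usr$admin_time, cohort, nurse,
                    user_testing_cost = ut_cost)
  inc <- incremental(cur, usr, cohort$wtp)
  iterations <- data.frame(
    delta_pades = inc$delta_pades,
    delta_mod_severe = inc$delta_mod_severe_pades,
    delta_qaly = inc$delta_qaly_decrement,
    ics = inc$incremental_cost_saving,
    nmb = inc$nmb_at_wtp,
    user_testing_cost = ut_cost,
    cur_pades = cur$total_pades,
    cur_mod_severe = cur$moderate_severe_pades,
    cur_qaly = cur$total_qaly_decrement,
    cur_cost = cur$health_system_cost,
    usr_pades = usr$total_pades,
    usr_mod_severe = usr$moderate_severe_pades,
    usr_qaly = usr$total_qaly_decrement,
    usr_cost = usr$health_system_cost
  )
  structure(list(
    iterations = iterations,
    summary = t(vapply(iterations, summarise_column, numeric(3))),
    p_cost_saving = mean(iterations$ics > 0),
    p_cost_effective = mean(iterations$nmb > 0),
    wtp = cohort$wtp,
    n = n_samples, seed = seed, cohort = cohort
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  fmt <- function(row) sprintf("%s (%s to %s)",
                               format(round(s[row, "mean"], 1), big.mark = ","),
                               format(round(s[row, "lower"], 1), big.mark = ","),
                               format(round(s[row, "upper"], 1), big.mark = ","))
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n, x$seed))
  cat(sprintf("  pADEs avoided:              %s\n", fmt("delta_pades")))
  cat(sprintf("  moderate-severe avoided:    %s\n", fmt("delta_mod_severe")))
  cat(sprintf("  QALY decrements avoided:    %s\n", fmt("delta_qaly")))
  cat(sprintf("  incremental cost-saving:  GBP %s\n", fmt("ics")))
  cat(sprintf("  net monetary benefit:     GBP %s (at GBP %s/QALY)\n",
              fmt("nmb"), format(x$wtp, big.mark = ",")))
  cat(sprintf("  P(cost-saving) = %.3f; P(cost-effective) = %.3f\n",
              x$p_cost_saving, x$p_cost_effective))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, recomputes the per-iteration net
#' monetary benefit `wtp * delta_qaly + ics` and reports the fraction of
#' iterations in which it is positive. At `wtp = 0` this equals the
#' probability of cost-saving; as `wtp` grows it approaches the fraction
#' of iterations with a positive QALY difference.
#'
#' @param psa_result A [run_psa()] result.
#' @param wtp_grid Non-empty vector of non-negative willingness-to-pay
#'   values (GBP/QALY).
#' @return A data frame of class `ceac_curve` with columns `wtp` and
#'   `p_cost_effective`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa_result, "psa_result"),
            length(wtp_grid) >= 1, all(wtp_grid >= 0))
  it <- psa_result$iterations
  p <- vapply(wtp_grid,
              function(w) mean(w * it$delta_qaly + it$ics > 0),
              numeric(1))
  structure(data.frame(wtp = wtp_grid, p_cost_effective = p),
            class = c("ceac_curve", "data.frame"))
}

#' Export the cost-effectiveness plane
#'
#' Writes one row per iteration with the incremental QALY gain
#' (`delta_qaly`, QALY decrements avoided) and the incremental cost
#' (`-ics`: a positive cost-saving is a negative incremental cost), and
#' reports the fraction of iterations in the dominant quadrant (positive
#' QALY gain, negative incremental cost).
#'
#' @param psa_result A [run_psa()] result.
#' @param path CSV output path.
#' @return Invisibly, a list with `path`, `n` and
#'   `dominant_quadrant_fraction`.
#' @export
ce_plane_export <- function(psa_result, path) {
  stopifnot(inherits(psa_result, "psa_result"))
  it <- psa_result$iterations
  plane <- data.frame(incremental_qaly_gain = it$delta_qaly,
                      incremental_cost = -it$ics)
  utils::write.csv(plane, path, row.names = FALSE)
  invisible(list(path = path, n = nrow(plane),
                 dominant_quadrant_fraction =
                   mean(it$delta_qaly > 0 & it$ics > 0)))
}

#' Running-mean convergence check
#'
#' Computes running means of the net monetary benefit, the incremental
#' cost-saving and the pADE reduction over the iteration sequence, and
#' flags the run converged when, for each quantity, the range of the
#' running mean over the final quarter of iterations is below `tol`
#' times the magnitude of its final value.
#'
#' @param psa_result A [run_psa()] result with at least `2 * block_size`
#'   iterations.
#' @param block_size Thinning interval for the reported series
#'   (default 100).
#' @param tol Relative stability tolerance (default 0.01).
#' @return A list: `series` (data frame of thinned running means),
#'   `converged` (logical), `relative_range` (per quantity).
#' @export
convergence_check <- function(psa_result, block_size = 100L, tol = 0.01) {
  stopifnot(inherits(psa_result, "psa_result"))
  it <- psa_result$iterations
  n <- nrow(it)
  if (n < 2 * block_size) {
    stop("need at least 2 * block_size iterations", call. = FALSE)
  }
  idx <- seq(block_size, n, by = block_size)
  running <- function(x) cumsum(x) / seq_along(x)
  series <- data.frame(
    iteration = idx,
    nmb = running(it$nmb)[idx],
    ics = running(it$ics)[idx],
    delta_pades = running(it$delta_pades)[idx]
  )
  tail_idx <- seq(ceiling(3 * n / 4), n)
  rel_range <- vapply(it[c("nmb", "ics", "delta_pades")], function(x) {
    rm_tail <- running(x)[tail_idx]
    final <- rm_tail[length(rm_tail)]
    if (final == 0) return(if (diff(range(rm_tail)) == 0) 0 else Inf)
    diff(range(rm_tail)) / abs(final)
  }, numeric(1))
  list(series = series, converged = all(rel_range < tol),
       relative_range = rel_range)
}
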