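sample_ut_draws <- function(ut, n) {
  draw_block <- function(specs) {
    do.call(cbind, lapply(specs, dist_sample, n = n))
  }
  list(interview = draw_block(ut$interview_minutes),
       analysis = draw_block(ut$analysis_minutes),
       revision = draw_block(ut$revision_minutes))
}

sample_arm_draws <- function(arm, n) {
  list(label = arm$label,
       node1 = rdirichlet_mat(n, arm$node1),
       severity = lapply(seq_len(N_ERROR_TYPES), function(i) {
         rdirichlet_mat(n, arm$severity[i, ])
       }),
       admin_time = dist_sample(arm$admin_time, n))
}

#' Sample joint parameter draws for the probabilistic analysis
#'
#' Draws `n` independent joint realisations of every stochastic model
#' input from the current RNG stream. Shared inputs (detection, no-harm,
#' costs, QALY decrements, user-testing durations) are sampled once per
#' iteration and used by both arms — common random numbers, which leave
#' arm means untouched but reduce the Monte Carlo variance of incremental
#' quantities. Arm-specific inputs (node-1 Dirichlet, per-type severity
#' Dirichlets, administration time) are sampled independently per arm.
#'
#' Node-1 and node-4 Dirichlets are sampled independently of each other
#' within an arm; truncation clamps follow each family's specification.
#'
#' @param arms List of two [arm_spec()]s (`current`, `user_tested`).
#' @param shared A [shared_spec()].
#' @param n Number of joint draws.
#' @return An object of class `param_draws`: matrices/vectors with one
#'   row (element) per iteration.
#' @export
sample_draws <- function(arms, shared, n = 1) {
  stopifnot(n >= 1)
  shared_draws <- list(
    p_undetected = dist_sample(shared$p_undetected, n),
    p_no_harm = dist_sample(shared$p_no_harm, n),
    cost_detected = dist_sample(shared$cost_detected, n),
    cost_pade = do.call(cbind, lapply(shared$cost_pade, dist_sample, n = n)),
    qaly_decrement = do.call(cbind, lapply(shared$qaly_decrement,
                                           dist_sample, n = n)),
    ut = sample_ut_draws(shared$user_testing, n)
  )
  structure(list(n = n,
                 arms = lapply(arms, sample_arm_draws, n = n),
                 shared = shared_draws),
            class = "param_draws")
}

#' Draw a single joint parameter realisation
#'
#' Convenience wrapper around [sample_draws()] with `n = 1`: the unit of
#' one probabilistic-analysis iteration. With the same RNG state the same
#' draw is returned.
#'
#' @inheritParams sample_draws
#' @return A `param_draws` object with `n = 1`.
#' @export
sample_draw <- function(arms, shared) {
  sample_draws(arms, shared, n = 1)
}

#' Expected-value parameter draw
#'
#' Builds a degenerate `param_draws` object (n = 1) in which every input
#' sits at its analytic mean: Dirichlet vectors at their normalised
#' pseudo-counts, the lognormal detection probability at
#' `exp(mu + sigma^2/2)`, and so on. This is the model's deterministic
#' expected-value analysis and the closed-form oracle against which Monte
#' Carlo means are checked.
#'
#' @inheritParams sample_draws
#' @return A `param_draws` object with `n = 1`.
#' @export
expected_value_draw <- function(arms, shared) {
  mean_block <- function(specs) {
    matrix(vapply(specs, dist_mean, numeric(1)), nrow = 1)
  }
  ev_arm <- function(arm) {
    list(label = arm$label,
         node1 = matrix(dist_mean(dist_spec("dirichlet", arm$node1)),
                        nrow = 1),
         severity = lapply(seq_len(N_ERROR_TYPES), function(i) {
           matrix(dist_mean(dist_spec("dirichlet", arm$severity[i, ])),
                  nrow = 1)
         }),
         admin_time = dist_mean(arm$admin_time))
  }
  ut <- shared$user_testing
  structure(list(
    n = 1L,
    arms = lapply(arms, ev_arm),
    shared = list(
      p_undetected = dist_mean(shared$p_undetected),
      p_no_harm = dist_mean(shared$p_no_harm),
      cost_detected = dist_mean(shared$cost_detected),
      cost_pade = mean_block(shared$cost_pade),
      qaly_decrement = mean_block(shared$qaly_decrement),
      ut = list(interview = mean_block(ut$interview_minutes),
                analysis = mean_block(ut$analysis_minutes),
                revision = mean_block(ut$revision_minutes))
    )), class = "param_draws")
}

#' Extract one iteration of a `param_draws` object
#'
#' @param draws A `param_draws` object.
#' @param i Iteration index.
#' @return A `param_draws` object with `n = 1` holding iteration `i`.
#' @export
draw_slice <- function(draws, i) {
  stopifnot(inherits(draws, "param_draws"), i >= 1, i <= draws$n)
  slice_arm <- function(a) {
    list(label = a$label,
         node1 = a$node1[i, , drop = FALSE],
         severity = lapply(a$severity, function(m) m[i, , drop = FALSE]),
         admin_time = a$admin_time[i])
  }
  sh <- draws$shared
  structure(list(
    n = 1L,
    arms = lapply(draws$arms, slice_arm),
    shared = list(
      p_undetected = sh$p_undetected[i],
      p_no_harm = sh$p_no_harm[i],
      cost_detected = sh$cost_detected[i],
      cost_pade = sh$cost_pade[i, , drop = FALSE],
      qaly_decrement = sh$qaly_decrement[i, , drop = FALSE],
      ut = list(interview = sh$ut$interview[i, , drop = FALSE],
                analysis = sh$ut$analysis[i, , drop = FALSE],
                revision = sh$ut$revision[i, , drop = FALSE])
    )), class = "param_draws")
}
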