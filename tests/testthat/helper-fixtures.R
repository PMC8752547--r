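# Shared fixtures built in code. The base-case configuration is loaded
# once per test run; tests that mutate it must copy it first.

base_cfg <- base_case_config()

# Construct a minimal single-iteration param_draws object by hand, for
# tests that need full control over every input value.
manual_draw <- function(node1_current, severity_current,
                        node1_user = node1_current,
                        severity_user = severity_current,
                        admin_current = 13.3, admin_user = 11.9,
                        p_undetected = 0.78, p_no_harm = 0.9,
                        cost_detected = 0.5,
                        cost_pade = c(124, 1252, 1846),
                        qaly = c(0.004, 0.035, 3.5),
                        interview = c(24, 29, 23, 20),
                        analysis = c(94, 76, 53, 50),
                        revision = c(265, 140, 140)) {
  arm <- function(label, node1, sev, at) {
    list(label = label, node1 = matrix(node1, nrow = 1),
         severity = lapply(seq_len(11), function(i) {
           matrix(sev[i, ], nrow = 1)
         }),
         admin_time = at)
  }
  structure(list(
    n = 1L,
    arms = list(
      current = arm("current", node1_current, severity_current,
                    admin_current),
      user_tested = arm("user_tested", node1_user, severity_user,
                        admin_user)),
    shared = list(
      p_undetected = p_undetected, p_no_harm = p_no_harm,
      cost_detected = cost_detected,
      cost_pade = matrix(cost_pade, nrow = 1),
      qaly_decrement = matrix(qaly, nrow = 1),
      ut = list(interview = matrix(interview, nrow = 1),
                analysis = matrix(analysis, nrow = 1),
                revision = matrix(revision, nrow = 1)))
  ), class = "param_draws")
}

uniform_severity <- function() matrix(1 / 3, nrow = 11, ncol = 3)

# A small, fast PSA shared by several tests.
small_psa <- local({
  psa <- NULL
  function() {
    if (is.null(psa)) {
      psa <<- run_psa(base_cfg$arms, base_cfg$shared, base_cfg$cohort,
                      n_samples = 2000, seed = 42)
    }
    psa
  }
})
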