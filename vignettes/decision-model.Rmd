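---
title: "A probabilistic decision model for intravenous administration errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic decision model for intravenous administration errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mederrcea)
```

## The decision problem

Nurses preparing and administering intravenous medicines on hospital
wards rely on written guidelines. Redesigning a guideline through
*user-testing* — iterative rounds of interviews in which users reveal
where they misread or misunderstand the document, followed by revisions
— reduces the frequency of administration errors, but carries a one-off
cost. `mederrcea` models whether that cost is offset by the health-system
savings and health gains from fewer *preventable adverse drug events*
(pADEs), from the payer perspective of the hospital organisations using
the guideline.

Two strategies are compared for a single high-risk intravenous medicine
(the base case is parameterised for voriconazole): administration with
the **current** guideline and with a **user-tested** guideline.

## Model structure

Each administered dose passes through a four-node chance tree:

1. **Error type** — a 12-category multinomial: no error, or one of 11
   guideline-related error types (e.g. wrong diluent volume, wrong
   infusion rate). The two arms have different node-1 probabilities.
2. **Detection** — an erroneous dose may be caught before administration
   by a double-check from a second nurse. The probability the error
   *remains undetected* is the pooled risk ratio of an error persisting
   after double-checking, used directly as a probability and shared
   between arms.
3. **Harm** — an undetected error that reaches the patient causes no
   harm with probability `p_no_harm` (shared between arms).
4. **Severity** — a harmful undetected error (a pADE) is minor,
   moderate or severe, with an error-type-specific conditional
   distribution that differs between arms.

This yields 56 terminal paths per dose (`enumerate_paths()`): one
no-error path plus five per error type. Detected errors incur only a
small correction cost; pADEs incur a severity-specific treatment cost
and QALY decrement. Administration time itself differs between arms
(user-tested guidelines are faster) and is costed at the nurse hourly
rate at the cohort stage.

## Parameterisation

Error-type and severity probabilities are Dirichlet posteriors built by
conjugate updating of a weak prior with observed counts from a
randomised in-situ study of 273 nurses (133 current, 140 user-tested).
The prior places a pseudo-count of 0.1 on every joint
type-by-severity cell, so error types never observed retain a small
non-zero probability; because each error type spans three severity
cells, its node-1 category (and the no-error category) carries a prior
mass of 0.3. Observed counts may be fractional: an error whose severity
rating tied between two levels contributes half a count to each. The
bundled base case (`base_case_config()`) carries the resulting
pseudo-counts — for example error type 3 in the current arm is
Dirichlet(5.1, 5.6, 0.1), summing to the node-1 entry 10.8 — plus:

* detection: lognormal(−0.25, 0.086) on the log scale for the
  undetected-error risk ratio, derived from the 95% *prediction*
  interval (0.655–0.918) of a random-effects meta-analysis of three
  double-checking trials; draws are clamped to at most 1 because the
  value acts as a probability (clamping fires with probability
  ≈ 0.002);
* harm: Beta(217, 23) for `p_no_harm`, from a point-prevalence study in
  which 217 of 240 observed intravenous errors caused no harm;
* costs (GBP, 2018 prices): lognormal treatment costs per pADE severity
  and a lognormal correction cost for detected errors; deterministic
  staff rates (£65/h pharmacist, £37/h nurse);
* QALY decrements per pADE: normal, truncated at zero (0.004 minor,
  0.035 moderate, 3.50 severe);
* administration time per dose: normal, truncated at zero (13.3 min
  current, 11.9 min user-tested);
* user-testing resources: normally distributed interview, analysis and
  revision durations for a pilot round of 4 interviews and three rounds
  of 10, transcription at £1.75 per spoken minute, and fixed training
  (£562) and equipment (£4) costs. At mean durations the intervention
  costs £6,318.

The cohort is 4,000 doses per year for 5 years at a 3.5% annual
discount rate and a willingness-to-pay of £20,000 per QALY.

```{r base-case}
cfg <- base_case_config()
ev <- expected_value_draw(cfg$arms, cfg$shared)
sum(expected_dose_outcome(ev, "current")$p_pade_by_severity)      # per-dose pADE risk
sum(expected_dose_outcome(ev, "user_tested")$p_pade_by_severity)
user_testing_cost(ev, cfg$shared$user_testing, cfg$shared$staff_rates)
```

## Probabilistic analysis

`run_psa()` propagates joint parameter uncertainty with Monte Carlo
simulation (default 20,000 iterations, which `convergence_check()`
confirms is ample: the final-quarter running means of NMB, cost-saving
and pADE reduction move by well under 1%). Outputs per iteration are
the incremental pADE counts, QALY decrements, incremental cost-saving
(ICS) and net monetary benefit, NMB = λ·ΔQALY + ICS. Credible intervals
are empirical 2.5/97.5 percentiles.

```{r psa}
psa <- run_psa(cfg$arms, cfg$shared, cfg$cohort, n_samples = 20000, seed = 1)
psa
```

Design choices that the underlying sources leave open, resolved here
once and used throughout:

* **Discount timing.** Annual amounts for years *t* = 1…H are weighted
  by (1 + r)^−t, so the first year is discounted once (the factor sum
  for 5 years at 3.5% is 4.5151). The alternative convention (year 1
  undiscounted) inflates discounted totals by ≈ 3.5% and is
  inconsistent with the published totals this model reproduces. Event
  *counts* are never discounted; the one-off user-testing cost,
  incurred at the start of the horizon, is not discounted either.
* **Common random numbers.** Shared parameters (detection, no-harm,
  costs, QALY decrements, user-testing durations) take one draw per
  iteration used by both arms; arm-specific Dirichlets and
  administration times are drawn independently. Sharing leaves arm
  means untouched but narrows the Monte Carlo distribution of
  *incremental* quantities — standard practice when the sources publish
  one distribution per shared quantity. Credible-interval widths are
  therefore mildly sensitive to this choice; means are not.
* **Independent node sampling.** Node-1 and node-4 Dirichlets are
  sampled independently within an arm; nothing in the aggregated counts
  identifies a joint cell-level correlation beyond what the pseudo-count
  structure already encodes.
* **Truncation.** Normal durations and QALY decrements are clamped at
  zero and the detection risk ratio at one. At the base-case parameters
  every clamp is a far-tail event (≤ 0.2% of draws), so means shift
  negligibly.
* **Tie-breaks and degenerate inputs.** A deterministic distribution is
  allowed anywhere a stochastic one is, which is how the no-harm and
  detection sensitivity scenarios are expressed; an `n = 1` PSA is legal
  and summarises to itself.

## Scenario analyses

`built_in_scenarios()` covers the standard one-way analyses: horizons
of 1 and 10 years, 20,000 doses per year, deterministic no-harm
probabilities of 0.75 and 0.99, and deterministic detection at the
prediction-interval bounds (0.655, 0.918) — the last pair is this
package's choice of detection variant, since only the interval itself
is published.

The structural scenario `rescale_error_frequency()` adapts the model to
settings with fewer errors than the source study (which used an
unfamiliar, high-risk medicine): the current arm's error-type and
severity pseudo-counts are scaled uniformly by
*k* = target / (p_error × E\[p_undetected\]) so that the expected
undetected-error frequency hits a target (32% in the built-in scenario,
against ≈ 63% in the base case, giving *k* ≈ 0.507), with freed mass
moved to the no-error category. Scaling node 4 together with node 1
keeps every error type's conditional severity composition — and the
node-1/severity-sum consistency invariant — exactly intact. The
user-tested arm is scaled so its *relative* reduction in
undetected-error frequency is preserved (or multiplied by an
effectiveness factor; the built-in half-effect scenario uses 0.5,
implemented as halving that relative reduction and solving for the
user arm's uniform scale factor). Published results for the half-effect
variant were produced by a procedure whose details are not in the main
source and differ from this linear interpretation; the package's
numbers for that one scenario are its own, internally consistent
definition, and are directionally but not numerically comparable.

## Meta-analysis stage

`pool_random_effects()` implements DerSimonian–Laird inverse-variance
pooling of per-trial log risk ratios (0.5 continuity correction on all
four cells of a trial with a zero cell), with the 95% prediction
interval built from a t quantile on *k* − 2 degrees of freedom and
variance se² + τ². With the three published double-checking trials this
materially widens the interval relative to the confidence interval,
which is the behaviour the published input distribution reflects.
`to_lognormal_spec()` then converts a prediction interval to the
lognormal node-2 input: σ = (log U − log L)/(2 × 1.96), μ = pooled log
RR — applied to (0.655, 0.918) this recovers the published
lognormal(−0.25, 0.086) to rounding.

The z-based DerSimonian–Laird confidence interval is only near-nominal
when within-trial variance dominates the heterogeneity; the package's
simulation checks therefore use trials of several hundred
administrations per arm (τ = 0.05), where coverage is ≈ 94%. With very
large trials and the same τ it undercovers substantially — a known
property of the estimator with few trials, not a defect of the
implementation — which is why the prediction interval, not the
confidence interval, feeds the decision model.

## Synthetic data and what the tests show

`simulate_clinical_study()` draws multinomial counts over the 34 joint
cells (no error + 11 types × 3 severities) per arm, exactly the
structure the Dirichlet updating assumes, and
`simulate_double_check_trials()` generates two-arm binomial trials with
normal between-trial spread on the log risk ratio.
`end_to_end_recovery()` chains study simulation, posterior
construction and the PSA, and compares Monte Carlo means against
closed-form outcomes evaluated at the true parameter values.

These generators share the model's own distributional assumptions, so
passing recovery tests demonstrates internal correctness — that
posteriors, tree arithmetic and cohort scaling invert the generative
process — not that real observational data satisfy those assumptions.
In particular the simulators do not model observer error in severity
scoring, correlation between error types within a nurse, or
non-multinomial dose-level dependence.

Problem sizes used by the test-suite: 20,000-iteration runs for the
reproduction checks (each takes well under a minute), 1,000–2,000
iterations for distributional properties, 10⁵ participants per arm for
posterior recovery, and 1,000 replicate 3-trial sets for meta-analysis
coverage.

## Known limitations

* Litigation costs, drug-acquisition costs and societal-perspective
  costs are out of scope, as in the published analysis.
* A detected error is assumed corrected at the stated correction cost
  with no repeat-administration failure; evaluation is single-pass.
* One detection distribution and one no-harm distribution apply
  uniformly across all 11 error types.
* The QALY decrements attached to pADE severities derive from expert
  judgement in the source literature rather than primary outcome data;
  the wide severe-pADE decrement (3.50 ± 0.83 QALYs) dominates the NMB
  uncertainty.
* The half-effect structural scenario is the package's own linear
  definition, as discussed above.
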