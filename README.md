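# mederrcea

Probabilistic cost-effectiveness modelling of intravenous medicines
administration errors by nurses, and of guideline *user-testing* as the
error-reduction intervention.

## What it is for

Hospital nurses preparing intravenous doses follow written guidelines;
poorly designed guidelines cause administration errors, some of which
reach the patient and cause harm (preventable adverse drug events,
pADEs). User-testing — iterative interview-and-revision rounds that fix
the points where users misread a guideline — reduces error frequency at
a one-off cost. This package answers, from the health-system payer's
perspective: **does that one-off cost pay for itself in avoided error
costs and health losses?**

It is aimed at health-economics and medication-safety researchers who
want a transparent, fully reproducible implementation of the
decision-analytic model: every input is a declared distribution, every
result is recomputable from a seed.

## The model

Each dose traverses a four-node chance tree, populated separately for
the *current* and *user-tested* guideline arms:

1. error type *i* (11 guideline-related types, or no error) —
   Dirichlet-distributed probabilities, posterior to observed study
   counts with a 0.1 prior pseudo-count per type-by-severity cell;
2. the error remains undetected before administration with probability
   *p*<sub>u</sub> (lognormal; the pooled risk ratio of an error
   surviving a nurse double-check, from a random-effects meta-analysis
   prediction interval);
3. an undetected error causes no harm with probability *p*<sub>0</sub>
   (Beta(217, 23));
4. a harmful error is minor / moderate / severe with type-specific
   Dirichlet severity splits.

Per-dose outcomes are scaled to a cohort (4,000 doses/year, 5 years,
costs and QALYs discounted at 3.5%/year), administration time is costed
at nurse rates, and the user-testing intervention cost (interviews,
transcription, analysis, revisions, training; ≈ £6,318 at mean resource
use) is added once to the user-tested arm. Monte Carlo simulation
(20,000 draws) propagates joint parameter uncertainty; outputs are the
pADE reductions, incremental cost-saving
ICS = cost(current) − cost(user-tested), and net monetary benefit
NMB = λ·ΔQALY + ICS at willingness-to-pay λ = £20,000/QALY, with
cost-effectiveness acceptability curves over a λ grid.

## Worked example

```r
library(mederrcea)

cfg <- base_case_config()
psa <- run_psa(cfg$arms, cfg$shared, cfg$cohort, n_samples = 20000, seed = 1)
psa
#> Probabilistic sensitivity analysis: 20000 iterations (seed 1)
#>   pADEs avoided:              413.5 (210.1 to 681)
#>   moderate-severe avoided:    158.3 (-14.6 to 366.5)
#>   QALY decrements avoided:    147.4 (-26.3 to 417)
#>   incremental cost-saving:  GBP 241,964.2 (41,399.3 to 495,111.9)
#>   net monetary benefit:     GBP 3,188,974 (-367,839.2 to 8,685,248) (at GBP 20,000/QALY)
#>   P(cost-saving) = 0.992; P(cost-effective) = 0.960
```

Read: over 5 years of voriconazole administration across the cohort,
user-tested guidelines avoid a mean 413 pADEs (158 moderate-severe) and
147 QALYs of decrement; they save a mean £242k of health-system cost
(99% probability the saving is positive) and yield a mean net monetary
benefit of £3.19M, positive in 96% of simulations — i.e. user-testing
is very likely both cost-saving and cost-effective.

Scenario analyses and the other stages follow the same pattern:

```r
ceac(psa, wtp_grid = seq(0, 50000, 5000))        # acceptability curve
run_scenario_suite(cfg, n_samples = 20000)        # built-in sensitivity set
cfg32 <- apply_scenario(cfg, scenario_spec("f32", target_undetected_frequency = 0.32))
re <- pool_random_effects(read_trial_table("trials.csv"))  # node-2 input
to_lognormal_spec(re)
```

A thin command-line wrapper ships at `inst/cli/mederrcea.R`
(`run`, `suite` and `meta` subcommands).

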