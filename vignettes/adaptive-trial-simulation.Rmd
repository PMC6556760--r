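---
title: "Methods: simulating Bayesian adaptive and platform trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating Bayesian adaptive and platform trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hectsim)
```

## Scope and intent

`hectsim` estimates the operating characteristics of Bayesian adaptive and
platform trial designs by Monte Carlo: the user states a *truth scenario*
(per-arm outcome distributions, adherence, accrual economics) and a *design*
(thresholds, schedule, allocation, platform settings), and the package
simulates the trial as it would actually unfold, many times. Everything the
package reports — type I error, power, expected sample size, cost,
duration — is a Monte-Carlo average over such simulated trials; nothing is
an analytic approximation.

## The probability model

### Conjugate posteriors

Binary outcomes use the beta-binomial model: a Beta(α₀, β₀) prior on each
arm's response probability with a binomial likelihood, so the posterior
after s responses in n patients is Beta(α₀ + s, β₀ + n − s). Continuous
outcomes use a conjugate Gaussian model for the arm mean with the outcome
standard deviation treated as a plug-in: the posterior of the mean stays
Gaussian, with precision 1/τ₀² + n/σ̂².

The diffuse defaults are Beta(1, 1) for binary and N(0, 1000²) (outcome
units) for the continuous mean prior. These are the standard flat choices;
both are configurable (`prior` in `design_rules()`). We deliberately do
not model the outcome variance hierarchically: a normal-inverse-gamma
treatment would make interim decisions heavier for little planning
benefit. Instead σ̂ is the sample SD pooled across all arms with at least
two observations, recomputed at every interim analysis, with the
user-supplied planning SD (`planning_sd`) used before any arm has two
observations. The plug-in slightly understates uncertainty at very small
n; at the interim sizes where decisions actually fire the effect is
negligible.

### Decision probabilities

The quantity driving every adaptation is the posterior probability that an
arm is best. Closed forms do not exist for the "best of K" probability, so
it is estimated by Monte Carlo: `decision_draws` joint draws (default
10,000) from the per-arm posteriors, counting for each arm the fraction of
draws in which it is strictly best in the configured benefit direction.
The entries of the resulting vector sum to one exactly, since every joint
draw elects exactly one winner. Ties have probability zero for continuous
draws; for degenerate point-mass inputs the deterministic tie-break is the
lowest arm index. The two-arm quadrature oracle
(`prob_superior_pair_closed_form()`) exists purely to validate the Monte
Carlo path and is never used by the engine.

The margin ("MCID") rule uses `prob_effect_below_margin()`: the fraction
of joint draws in which the treatment-versus-control effect is strictly
below the margin. For binary outcomes the effect scale is the relative
risk reduction 1 − p_t/p_c in the harmful-event convention (the event is
bad, lower rates are better); the benefit direction therefore defaults to
`"lower-better"` for binary outcomes and must be declared by the user when
the convention differs. For continuous outcomes the scale is the mean
difference oriented so that positive is benefit.

## The trial engine

### Schedule and rule ordering

Interim looks are placed at equal increments of accumulated total sample
size — look j at ⌈j·max_n/n_looks⌉ patients — with the last look at
`max_n` serving as the final analysis. At each look the rules are
evaluated in a fixed order: superiority stop, then probability-of-best
futility drops, then margin drops, then platform admissions, then the
all-treatments-dropped futility stop. Superiority-first is a design
choice: when one arm has essentially won, terminating cleanly dominates
any ambiguity about simultaneously dropping its competitors. One
consequence worth knowing: in a two-arm trial in `"all-arms"` mode the two
probabilities are complementary, so with matched thresholds (say 0.99
superiority / 0.01 futility) the superiority rule always fires first and
a pure futility termination requires asymmetric thresholds or the margin
rule.

The control arm is never dropped by futility rules; treatment-effect
definitions need a persistent reference. The exception is the perpetual
platform transition, where the stage winner (possibly a treatment)
becomes the comparator for the next two-arm stage and every other arm —
including, if it lost, the original control — is retired with enrollment
frozen.

### Allocation

Equal allocation applies whenever response-adaptive randomization (RAR)
is disabled, before the global `burn_in` sample size, and for a
configurable `new_arm_burn_in` (default 50 patients) after a platform
admission so a cold-start arm is not starved. After burn-in, RAR
recomputes the superiority probabilities for *every accumulated patient*,
using a reduced draw count (`rar_draws`, default 1,000) for tractability,
and allocates with weights proportional to the square roots of those
probabilities. A floor (default 0.01) is imputed to each probability
before the square-root transform: without it, an arm whose probability
ever touched zero could never recover (allocation zero implies no data
implies probability stays zero). The floor is expressed relative to the
vector sum, which keeps the transform scale-free; for the normalized
vectors the engine produces this equals an absolute floor. A
`protect_control` option pins the control at 1/K, since reasonable people
disagree about whether the reference arm should be subject to RAR.

### Adherence, secondary outcomes, economics

Adherence is modeled as intent-to-treat dilution: with probability
1 − adherence a treatment-arm patient's outcome is drawn from the control
distribution, but the patient is analyzed on the assigned arm. Outcomes
are observable at accrual — no follow-up lag is modeled, which flatters
designs with many looks relative to trials with slow outcomes.

A secondary outcome, when configured, is accumulated and summarized with
the same conjugate machinery but never feeds any decision. It is drawn
from an RNG stream derived separately from the trial seed, so adding or
removing a secondary outcome provably does not perturb the decision path
(this is tested).

Cost is `total_n × cost_per_patient` and duration is
`total_n / accrual_rate`. Both are deliberately minimal linear models:
they make the cost/duration comparisons exact transforms of the
sample-size distribution, which is what a planning comparison needs.

### Platform and perpetual designs

Queued arms (`available_from > 0`) are admitted when an active arm is
dropped, at most one per dropped arm, capped by `max_active_arms`
(default: the number of initially active arms), and gated by their
`available_from` accrual point. An admitted arm starts from the diffuse
prior and enters allocation at the next patient. In perpetual mode a
superiority stop with a non-empty queue instead rolls into a new two-arm
stage; the look schedule continues past `max_n` with the same spacing up
to `perpetual_cap` (default 5 × max_n), where the trial is censored with
status `"perpetual-censored"` — unbounded continuation has to terminate
somewhere in a simulator.

### Determinism

`(scenario, seed)` determines a trial bit-for-bit. Design evaluation
seeds replicate i with `child_seed(master, i)`, a fixed Lehmer-style mix,
so extending `n_sims` appends replicates without reshuffling earlier
ones; the adaptive trial and its conventional comparator share each
child seed, making the comparison paired. Time-budget mode checks the
wall clock between replicates only, so every counted replicate is
complete and the realized count is recorded.

## Operating characteristics

Type I error is defined as the fraction of simulated trials under a null
configuration (all true parameters equal — validated, to guard mislabeled
nulls) that declare *any* winner, at an interim or final analysis. Power
is the fraction of trials under the alternative that declare the truly
best arm the winner. In `"all-arms"` mode the control can itself be
declared the winner; under the null this is exactly the two-sided
behavior that makes the flat-prior, one-look conventional design dual to
a classical two-sided test (the calibration check in the acceptance
suite). `"vs-control"` mode replaces the best-of-all probability with
pairwise versus-control probabilities for both stopping and dropping; the
two modes genuinely differ for K > 2 and the configuration names the one
in force. Summaries report both mean and median for cost (and everything
else), since the aggregation the field expects is not standardized.

Histograms of final sample size and cost use 20 equal-width bins over the
observed range with edges reported; a degenerate range (the conventional
design's constant n) widens to a unit bin around the point mass.

## What the generator emulates — and what a green test establishes

The scenario fixtures state worlds typical of event-driven global-health
trials: a 40% control event rate, treatments at the null (0.40), at a 50%
relative risk reduction (0.20), or intermediate (0.25); worked thresholds
of 99% superiority, 1% futility, and a 20% RRR margin at 95% certainty;
`max_n` = 2000 with 10 looks; a cost of 500 currency units per patient
and accrual of 10 patients per time unit (so durations read as weeks at a
moderate multi-site pace). The continuous fixture uses a 0.4-SD
standardized effect, `max_n` = 500.

The generator draws i.i.d. outcomes: no secular trends in the control
rate, no site effects, no covariates, no follow-up lag, no missingness
beyond the crossover-style adherence model. A green operating
characteristic therefore establishes that the *decision machinery* has
the stated frequentist properties in the stated i.i.d. world — not that a
real trial with drift or delayed outcomes would enjoy them. Those are
real phenomena (concurrent-control debates in platform trials exist for a
reason) and are out of scope here.

One saturation effect found while validating is worth recording: the
probability that a null-effect arm is dropped by the margin rule before
`max_n` converges to 1 as `max_n` grows, so adjacent values for large
`max_n` (2000 vs 8000 in the acceptance grid) differ by less than the
Monte-Carlo resolution of 1000 replicates. The monotone trend and the
500-vs-2000 separation are clearly resolved; the 2000-vs-8000 separation
is not resolvable at that replicate count, and the corresponding
acceptance assertion documents this rather than widening its tolerance.

## Numerical and interface choices

* Strict inequalities everywhere a draw is compared ("strictly best",
  "strictly below margin"); ties broken toward the lowest arm index.
* Monte-Carlo probabilities at 10,000 draws have SE ≤ 0.005; thresholds
  like 0.99 are therefore fuzzy at the half-percent scale. This is
  faithful to how such simulators operate; users needing sharper
  decisions raise `decision_draws`.
* Configs are JSON (`jsonlite`), validated completely before any
  simulation: unknown keys are rejected by name, range violations name
  the field and the allowed range, omitted fields take documented
  defaults and the defaulting is logged.
* Two-sided alpha throughout the sample-size calculator; Bonferroni over
  the (K − 1) treatment-vs-reference comparisons as the labeled
  multiplicity adjustment; unpooled variance for proportions, continuity
  correction off by default (both flagged in the output's method string).

## Known limitations

Binary and continuous outcomes only (no time-to-event); no informative
priors elicitation; no covariate or block randomization; no follow-up
lag; no alpha-spending interims (the designs are purely
Bayesian-threshold-driven); single-process execution. The perpetual mode
reports a censoring status rather than simulating indefinitely.
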