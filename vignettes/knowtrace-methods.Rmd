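---
title: "Adaptive knowledge tracing for arithmetic intervention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive knowledge tracing for arithmetic intervention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowtrace)
```

`knowtrace` implements the computational core of an adaptive tutoring engine
for arithmetic intervention in children with dyscalculia: which skill to
teach next, how confident we are that a skill is mastered, and what a wrong
answer reveals about the underlying misconception. This vignette describes
each model, its assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## The skill space: a prerequisite DAG

Arithmetic skills form a partial order: you cannot carry across the tens
boundary before you can add single-digit numbers. The package represents
this as a directed acyclic graph whose edge `A -> B` means *mastering A is a
necessary condition for mastering B*. Skills carry an operation (addition,
subtraction, multiplication), a number range (`0-10`, `0-100`, `0-1000`),
a `difficulty_rank` that must strictly increase along every same-operation
edge, and variant tags (`support`, `bridging_to_10`, `mental`).

`default_skill_graph()` ships a 38-skill roster: six skills per range for
addition and for subtraction (36) plus two multiplication skills. The
addition 0&ndash;100 slice follows the canonical chain

> 1,1 &rarr; 2,1 with support &rarr; 2,1 &rarr; 2,1 with bridging to 10
> &rarr; 2,2 &rarr; 2,2 with bridging to 10,

where "bridging to 10" marks tasks whose units digits sum past ten (a
carry), and the subtraction ladder mirrors it (a borrow). The exact
membership of the roster is a documented reconstruction — the full list is
not published anywhere — so it is deliberately editable: serialize with
`write_skill_graph()`, edit the JSON, read it back. A DAGitty-dialect
(`dag { "A" -> "B" }`) import/export is provided for interoperability with
causal-diagram tooling; that format carries structure only, so metadata is
reconstructed on import (operation from the label, rank from longest-path
depth).

Topological order breaks ties by `(difficulty_rank, id)` so that every
downstream computation — and therefore every tutoring session — is exactly
reproducible.

## The student model: windowed DBN knowledge tracing

Each skill has a latent binary mastery state $K_t \in \{0, 1\}$ evolving as
a two-state Markov chain and observed only through task performance — the
classic knowledge-tracing setup, stacked per skill over a dynamic Bayesian
network with one slice per practice step.

**Initialization.** $P(K_0 = 1) = 0.5$ for every skill: with no information
about the learner, the maximum-entropy prior.

**Transition.** $P(K_t = 1 \mid K_{t-1} = 1) = p_\mathrm{retain} = 0.9$ and
$P(K_t = 1 \mid K_{t-1} = 0) = p_\mathrm{acquire} = 0.1$ by default. The
forward (sum-product) message is the predictive mastery probability

$$ m_t = p_\mathrm{retain} \, p_{t-1} + p_\mathrm{acquire} (1 - p_{t-1}), $$

and 0.5 is its fixed point at the defaults, so an unobserved skill stays at
the uninformed prior.

**Emission.** The source framework conditions the update on hint, attempt,
correct, wrong and specific-wrong counts but leaves the likelihood
unspecified, so the package uses the minimal standard model: slip/guess
Bernoulli products, $P(\text{correct} \mid K = 1) = 1 - s$ (default
$s = 0.10$) and $P(\text{correct} \mid K = 0) = g$ (default $g = 0.20$),
with specific wrong answers counted inside the wrong count. Hints can
optionally discount correct-answer evidence (`hint_discount`, default off);
attempts and response time are carried in the observation but do not enter
the likelihood — there is no principled functional form to put them in.

**Update.** The posterior is the normalized two-term product
$p_t \propto P(\text{obs}_t \mid K_t = k) \, [m_t, 1 - m_t]$. (The printed
recurrence in the source's equation block double-counts the messages in its
denominator as typeset; the package implements the standard normalized
forward update that the surrounding derivation clearly intends.)

**Memory of five.** Posteriors are a function of at most the last five
observations per skill: the window is trimmed and the forward recursion
re-run from the 0.5 prior over what remains. While the window is filling
this equals the incremental update; afterwards it bounds how much history
can dominate fresh evidence, without inventing a decay parameter. The
window length is configurable (`memory`). The property suite verifies the
windowed recursion against brute-force marginalization over all $2^{T+1}$
latent paths to $10^{-12}$.

**Cross-skill propagation.** Solving tasks on one skill also says something
about its neighbours. The package applies a damped one-hop heuristic with
factor $\lambda$ (default 0.5): precursors move to
$\max(p_\mathrm{own}, \lambda p)$, successors to
$\min(p_\mathrm{own}, 1 - \lambda (1 - p))$. Both moves are monotone and
clamped, so they cannot destabilize the posterior field; $\lambda = 0$
disables them. Full belief propagation over the DAG is deliberately out of
scope — the framework asserts the influence but no mechanism, and a
one-hop bound is transparent and order-deterministic.

## The pedagogical controller

The controller keeps a posterior band $[\mathrm{PLT}, \mathrm{PUT}]$ around
the current skill. After each task:

* posterior above PUT &rarr; **ADVANCE** to the successor with the lowest
  `(difficulty_rank, id)`;
* posterior below PLT &rarr; **REMEDIATE** to the precursor with the
  *lowest* mastery posterior — the prerequisite the learner most plausibly
  lacks;
* otherwise **STAY**.

Out-of-band events adapt the crossed threshold by
`adapt_amount / n_samples` (default step 0.1, with `n_samples` counted from
the first task, so the adaptation decays like $1/n$ and the band stabilizes
as evidence accumulates): consistently strong learners get an easier
advancement bar, consistently struggling ones trigger remediation earlier.
The band is clamped to $0 \le \mathrm{PLT} \le \mathrm{PUT} \le 1$ at every
step, an invariant the test suite checks over whole sessions.

Two design repairs were needed to make the published control loop a working
algorithm, both configurable rather than silent:

1. **Branch orientation.** The pseudocode as printed sends an
   *above*-threshold posterior to the *precursor* task, contradicting its
   own prose ("moves them forward to the next level of difficulty") and the
   remediation rule. The default `semantics = "mastery_advance"` follows
   the prose; `semantics = "as_printed"` preserves the literal pseudocode
   for comparison.
2. **Threshold initialization.** Initializing the band to $[0, 1]$ (as the
   pseudocode does) is degenerate: a posterior can never leave $[0, 1]$, so
   neither branching nor threshold adaptation would ever run, and the
   printed initialization also divides by `n_samples = 0` on the first
   adaptation. Sessions therefore start the band at interior values
   (`plt0 = 0.3`, `put0 = 0.95`): below 0.3 a skill is likely missing a
   prerequisite, above 0.95 it is mastered enough to move on. The literal
   initialization remains reachable via `controller_config(plt0 = 0,
   put0 = 1)`, and the division is guarded by `max(n_samples, 1)`.

A session (`run_session()`) starts at the first skill in topological order,
plays one generated task per step, and stops teaching a skill once its
posterior is at least `mastery_stop` (default 0.95) on `consecutive_stop`
(default 2) consecutive tasks, jumping to the next unfinished skill in
topological order. The session ends when the final skill in that order is
mastered, or at `step_cap` (default 500) tasks, in which case the log is
flagged truncated rather than erroring. Given the same graph, learner,
configuration and seed, the emitted log is bit-identical.

## Task generation and buggy-rule diagnosis

`generate_task()` draws operands uniformly from each skill's constraint set
(digit pattern from the skill name, range cap, carry/borrow variant) by
rejection sampling; subtraction tasks always satisfy
$a \ge b$. The five diagnostic error cases are implemented as *executable
buggy rules* (`buggy_answer()`), each reproducing a characteristic
misconception:

| Case | Memory subtype | Rule | Example |
|------|----------------|------|---------|
| 1 | semantic | multiply instead of add/subtract | 3 + 5 = 15 |
| 2 | visuospatial | per-column sums, all digits concatenated, no carry | 28 + 14 = 312 |
| 3 | procedural | every digit collapsed into one sum | 92 + 43 = 18 |
| 4 | procedural | per-column sums keep only the units digit | 39 + 25 = 54 |
| 5 | semantic | any column containing a zero yields zero | 26 + 20 = 40 |

`classify_error()` returns `CORRECT` whenever the answer is right — buggy
rules can coincide with the truth on carry-free tasks, and a right answer
is never pathologized — and otherwise evaluates the rules in fixed
precedence Case 1 &rarr; Case 5, reporting every match and the first as the
primary diagnosis; unmatched wrong answers are `GENERIC_WRONG`. Choices
worth noting: the zero-effect rule is column-level (matching its worked
example) rather than whole-result-zero; subtraction analogues of Cases
2&ndash;4 are borrow-omission mirrors (absolute column differences,
digit-sum difference, per-column `(a - b) mod 10`); and the stray printed
example "32 + 7 = 109" matches no stated rule (the product would be 224),
so it classifies `GENERIC_WRONG` and is excluded from the reproduction
set.

## Simulated learners

No raw learner data are published, so the package evaluates itself on
synthetic cohorts. A `learner_profile()` has latent per-skill mastery,
slip/guess response noise, a per-practice learning rate, an error profile
over the five cases plus a generic residual (with subtype presets weighting
the cases by their memory system), and a lognormal response-time model
whose log-median grows linearly with difficulty rank
($\mathrm{rt} \sim \mathrm{LogNormal}(\log \mu_0 + \Delta\mu \cdot
\mathrm{rank}, \sigma)$; defaults 8 s, 0.15, 0.4 — so the hardest default
rank is roughly $e^{0.15 \cdot 17} \approx 13$ times slower than the
easiest, matching the qualitative pattern that response times climb with
level).

When a response is wrong, the drawn buggy rule produces the answer; if that
rule's output happens to equal the correct result, an unpatterned wrong
answer is substituted, so the correct rate is exactly
$p(1-s) + (1-p)g$ — the quantity the Monte-Carlo tests check against.

Cohorts (`simulate_cohort()`) mix a typical and a dyscalculic group.
Each learner starts having mastered a prefix of every operation chain up to
a sampled frontier rank. Defaults: typical learners start at frontier
8&ndash;16 with per-practice learning rates 0.2&ndash;0.4 and slip
0.02&ndash;0.08; dyscalculic learners start at frontier 0&ndash;6 with
learning rates 0.005&ndash;0.03 and slip 0.1&ndash;0.2 (guess 0.1&ndash;0.25
for both). The learning-rate scale is set by the session horizon: a
per-practice rate of 0.1 would master any skill after about seven
remediation steps, erasing the persistent-difficulty profile within a
single 500-step session; rates of order 0.01 keep genuine non-mastery
present at session end, which is what the calibration check needs to be a
check at all. Learner $i$ runs under `seed + i`, so cohorts are
reproducible and any single session can be replayed in isolation.

**What the generator does not emulate:** engagement and affect, forgetting
(mastery never unlearns), item-level difficulty within a skill,
hint-seeking strategies (hints default to zero), and any empirical
prevalence of the five error cases — none is published, so the subtype
weights are stated defaults. Passing calibration on these cohorts shows the
inference machinery recovers the generator's latent states; it does not
certify performance on real children.

**Calibration.** On a 50-learner default cohort the end-of-session
posteriors are compared with true latent mastery over all (learner, skill)
pairs with at least one observation — unvisited skills sit at the 0.5 prior
and say nothing about discrimination. The acceptance suite requires ranking
accuracy (ROC AUC) above 0.8 and Brier score below 0.20 against the
uninformed baselines of 0.5 and 0.25; the observed values are above 0.9
and below 0.02 respectively across the seeds exercised in the suite.

## Assessment analytics

* `per_skill_stats()` — sample variance ($n-1$ divisor) and SD per skill
  for speed and accuracy channels.
* `pearson_cor()` / `speed_accuracy_correlation()` — the speed–accuracy
  trade-off correlation. The packaged 11-skill pre-assessment dispersion
  table reproduces the published coefficients ($r = -0.5176$ for the
  variance channel, $-0.5034$ for the SD channel), which are
  divisor-agnostic because they are computed *from* the printed dispersion
  values. The published "standard error" column beside those coefficients
  matches no standard formula for a correlation's sampling error, so the
  result instead carries the regression standard error of the estimate,
  clearly labelled, and no test asserts the published SE values.
* `welch_anova()` — Welch's heteroscedastic one-way ANOVA, the appropriate
  test for response-time differences across difficulty levels when group
  variances differ. The published F values depend on unpublished raw data
  and are not reproduction targets; the implementation is instead validated
  to $10^{-8}$ against `stats::oneway.test` and an independently coded
  textbook formula, and checked to land within 5% of the classic F when
  sample variances and sizes are equal.
* `power_paired_t()` — a-priori power for the two-tailed paired $t$ test:
  smallest $N$ with noncentral-$t$ rejection probability at the target,
  $\delta = d_z\sqrt{N}$. For $d_z = 0.56$, $\alpha = 0.05$, power 0.95 it
  returns $N = 44$, $\delta = 3.7146$, $t_{crit} = 2.0167$, achieved power
  0.9526, agreeing with `stats::power.t.test` and a 100,000-replicate
  simulation.
* `summarize_sessions()` — a mean/min/max/count metric table over session
  logs (correct, wrong and specific-wrong answers per level and per
  skill-block, plus distinct-error-case counts), mirroring the layout used
  for cohort summaries.

## Numerical choices and limitations

Problem sizes in the test and acceptance suites are chosen to exercise the
mathematics, not to mimic deployment scale: brute-force DBN verification
enumerates up to $2^{10}$ latent paths per stream over 200 streams,
calibration uses 50 learners capped at 500 steps each, and the power
Monte-Carlo uses $10^5$ replicates. All randomness flows through R's RNG
under explicit seeds. Degenerate inputs are contracts, not crashes:
zero-variance groups and constant series are errors in the analytics;
empty graphs terminate sessions immediately; leaf/root boundary actions
degrade to STAY; step caps truncate and flag rather than throw.

Known limitations: no parameter learning (slip/guess/transition are
configuration, not fitted); no affective or trait inference; one task per
skill per step; the 38-skill roster is a reconstruction; and the one-hop
propagation is a bound, not posterior inference over the full DAG.
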