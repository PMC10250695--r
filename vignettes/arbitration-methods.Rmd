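---
title: "Methods: model-based/model-free dissociation in a three-stage Markov task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based/model-free dissociation in a three-stage Markov task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling choices behind `arbitrl`: the task
model, the two learning systems and their likelihood, what the synthetic
agents emulate (and what they do not), and the numerical decisions that a
user re-analysing choice data should know about.

## The task model

Each subject plays an individual decision tree with one root state, `n2`
stage-2 states and `n3` terminal states (default 1–4–8). Every non-terminal
(state, action) pair has exactly two candidate successors in the next
stage; which of the two is the *likely* one is fixed when the tree is
generated, so that it is learnable. Transitions deliver the likely
successor with probability 0.9 (low uncertainty) or 0.5 (high uncertainty).
Terminals carry coins valued 0/10/20/40 colored gray/yellow/red/blue; the
default label multiset is two of each. In the flexible condition every coin
pays its face value; in the specific condition only the cued goal color
pays. Sessions are 56 blocks — 14 per (condition × uncertainty) type in a
uniformly random order — with per-block trial counts drawn uniformly from
3–5 (low) or 5–7 (high) trials, giving an expected 280 trials. An optional
training phase (80 flexible trials, then 20 specific trials with a goal
color drawn per trial) can be generated; it is excluded from fitting and
metrics, since only main-phase behavior is analyzed.

Where the task description leaves the design open we fixed, once:

- **Topology.** The stage sizes are not dictated by "2-choice, 3-stage";
  1–4–8 with two candidate successors per pair is the smallest graph
  consistent with two-alternative choices and (p, 1−p) transition pairs,
  and is configurable via `tree_config()`.
- **Goal attainability.** Trees are resampled until every rewarded color is
  reachable from the root, otherwise specific goals could be unattainable.
- **Successor sampling.** The two candidates of each pair are drawn
  uniformly without replacement from the next stage; different actions may
  share successors.
- **Goal color** is drawn uniformly per specific block and may repeat
  across consecutive blocks (no constraint was stated).
- **States** are 0-based integers grouped by stage; actions are 0 = left,
  1 = right. This is the on-disk convention of the session CSV as well.

The optimal-policy oracle (`optimal_policy_value()`) runs backward
induction on the *true* transition probabilities and the goal-gated
rewards. Choice optimality scores the first decision against the optimal
set at the root and the second against the optimal set at the stage-2 state
actually reached; any action tied for optimal (within `1e-9`) counts as
optimal. Under high uncertainty ties are common, which is why
choice-optimality values there sit well above 25% even for random
responders. Note that "optimal sequence" is closed-loop: the brute-force
equivalent enumerates all deterministic policies (root action × an action
per stage-2 state), not just the four fixed (a1, a2) sequences — the two
coincide except when the optimal second action differs between the two
candidate stage-2 states.

## The two learners and the likelihood

The **model-free** system is SARSA with discount fixed at 1: on each
transition `δ_RPE = r + Q(s′,a′) − Q(s,a)` and `Q(s,a) += α δ_RPE`. The
intermediate (stage-1 → 2) reward is 0; the terminal reward is the *paid*
coins — in the specific condition the habit system experiences the
goal-gated payout, not the displayed coin value. The bootstrap term is 0 at
terminals. Q is initialized at 0 and persists across blocks and conditions
(continuous learning over the session; no resets).

The **model-based** system learns a transition matrix restricted to the two
candidate successors of each pair, initialized uniform (0.5, 0.5). After
each observed transition, `δ_SPE = 1 − T(s,a,s′)` and the observed entry
moves by `η δ_SPE` while the non-observed candidate is rescaled by
`(1 − η)` — the rescaling is implied rather than stated by the update rule,
but it is the only convention that keeps each row a probability
distribution, without which backward planning would be meaningless. At the
start of every trial the planner rebuilds `Q_MB` by a backward sweep over
stages 3 and 2 under the current goal (both of a trial's decisions use the
trial-start plan; transition updates from the current trial enter the next
trial's plan).

Both systems choose by softmax with their own inverse temperature,
computed with max-subtraction. Fitting replays a session in order: at each
decision the probability of the *chosen* action is computed from the
current values, then the learner is updated with the *observed* outcome —
so the state trajectory of the learner is determined by the data alone.
The per-trial likelihood is the product of the trial's two decision
probabilities; this trial-level product (rather than single decisions) is
what the preference and switching measures consume, matching the
trial-granularity of the mixture agents below.

Free parameters (2 per system) and their fitting ranges:

| parameter | meaning | valid range | restart draw |
|---|---|---|---|
| `α`, `η` | learning rates | (0, 1) | uniform (0.01, 0.99) |
| `τ` | inverse temperature (1/coins) | > 0 | log-uniform (0.01, 10) |

`τ` is in units of inverse coins; with value differences of ~10–30 coins,
behaviorally plausible values are roughly 0.05–0.3. Optimization is
Nelder–Mead in an unconstrained space (logit for rates, log for `τ`) from
200 random restarts by default. The restart draws are consumed one
(rate, τ) pair per restart so restart sequences are *nested*: increasing
`n_restarts` under the same seed can only improve the best NLL. `optim()`
exposes a relative tolerance rather than absolute simplex tolerances; we
use `reltol = 1e-8` with at most 2,000 evaluations per restart. Decision
probabilities are floored at `1e-12` before logging. Missing (timeout)
trials contribute no decisions and no learner updates — without an
observed choice there is nothing to update with. The replay exists twice:
a plain-R reference built from the exported learner primitives and a C++
fast path used by the fitter; the suite asserts their exact agreement.

## Strategy metrics

- **MB preference**: % of non-missing trials in a condition where the MB
  per-trial likelihood strictly exceeds the MF one. Ties count as non-MB;
  they have measure zero for continuous likelihoods but arise in edge-case
  tests.
- **System switching**: % of consecutive pairs of the condition-masked,
  non-missing trial sequence whose dominant system differs. Ties inherit
  the previous trial's dominance; block boundaries within a condition are
  not breaks; pairs never straddle conditions because the measure is
  per-condition.
- **Arbitration score**: MB preference (specific) / MB preference
  (flexible); undefined when the flexible preference is 0.
- **Performance**: mean paid coins per non-missing trial and choice
  optimality against the true-environment oracle (deliberately not the
  subject's learned model).

## The synthetic agents: what a green test establishes

`agent_spec()` + `simulate_session()` run both learners forward and let a
per-trial mixture weight `w` decide which system's softmax controls both
decisions of a trial (one controller per trial, matching the per-trial
preference measure; both learners always update from experienced
outcomes). Arbitration ability is operationalized as condition-dependent
weights: an intact arbitrator has `w_specific` near 1 and `w_flexible`
near 0; an impaired one has the weights pulled together — the ground-truth
analogue of an arbitration-score ratio near 1. Defaults chosen once for
the cohort generator: learning rates uniform in (0.2, 0.6) (MF) and
(0.3, 0.7) (MB), inverse temperatures uniform in (0.05, 0.2), lapse rate
0.02, missing rate 0.01, intact weights (0.85–1, 0–0.15), impaired
(0.55–0.75, 0.25–0.45), 30 subjects per group by default (the scale of the
clinical cohorts this stands in for). Every subject gets an individual
tree, as in the task.

The generator emulates: the block schedule, probabilistic transitions,
goal-gated payouts, continuous two-system learning, stochastic choice,
lapses and timeouts. It does **not** emulate: response times and the 2 s
deadline (beyond the missing flag), within-trial switches of control,
any online reliability-based arbitrator (control weights are fixed per
condition rather than computed from prediction errors), parameter drift,
or symptom/covariate structure. Green pipeline tests therefore establish
that the estimation and metrics recover the ground truth of *this* data
generating process — not that the fitted model is the true account of
human behavior, and cohort-specific human values (group means, F and t
statistics) are not reproducible targets.

## Design decisions taken where the sources were open

- The softmax denominator's printed `exp(rQ)` is read as a typo for
  `exp(τQ)`, as in the numerator.
- The MF learner updates from `reward_paid` only; goal-irrelevant coins
  shown but not paid do not reinforce.
- Each learner is fitted independently with its own `τ` (the two-system
  comparison is descriptive; no online arbitrator is estimated).
- Per-trial (not per-decision) likelihood products feed the preference
  measures; a per-decision variant is a trivial change of aggregation of
  the returned `decision_prob` matrix.
- Goal color is a block attribute in the main phase (the schedule's data
  contract), and a trial attribute in training.
- Paired t on identical columns is reported as t = 0, p = 1 rather than an
  error (0/0 in the textbook formula).
- Post-hoc contrasts are computed from the fitted linear model and
  reported both uncorrected and Tukey-corrected, since the correction
  procedure was unspecified; classic pooled-variance ANOVA is the default,
  Welch available by flag.

## Known limitations

- The planner assumes the tree's candidate-successor structure is known to
  the subject (only the probabilities are learned); there is no
  state-space learning.
- Fitting is per-subject maximum likelihood; no hierarchical pooling, no
  information criteria beyond raw NLL.
- With ~280 trials, inverse temperatures are recovered less precisely than
  learning rates; parameter-recovery tolerances in the acceptance suite
  are calibrated on the learning rates.
- The C++ replay is specific to the two-successor tree family; more
  general graphs would need the (slower) R reference path generalized.
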