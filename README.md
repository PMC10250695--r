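# arbitrl

Simulation and analysis toolkit for dissociating **model-based (MB,
goal-directed)** and **model-free (MF, habitual)** reinforcement learning —
and the arbitration between them — in a 2-choice, 3-stage Markov decision
task.

The task: on every trial a subject starts at the root of an individual
decision tree, makes two left/right choices, passes through probabilistic
state transitions (likely/unlikely successor with probability 0.9/0.1 in
low-uncertainty blocks, 0.5/0.5 in high-uncertainty blocks), and lands on a
terminal state carrying colored coins (gray/yellow/red/blue worth
0/10/20/40). In *flexible* blocks every coin pays; in *specific* blocks only
the cued goal color pays, so doing well requires planning over an internal
model of the transitions. Sessions comprise 56 randomly ordered blocks (14
per condition × uncertainty type, 3–5 or 5–7 trials each, ~280 trials in
expectation).

Two learners are fitted independently to each subject's choices:

- **MF (SARSA):** caches action values updated by reward prediction errors,
  `δ_RPE = r + γ Q(s′,a′) − Q(s,a)`, `Q(s,a) ← Q(s,a) + α δ_RPE`, with
  `γ = 1` fixed. Free parameters: learning rate `α`, softmax inverse
  temperature `τ`.
- **MB (forward learner + backward planner):** learns the transition matrix
  from state prediction errors, `δ_SPE = 1 − T(s,a,s′)`,
  `T(s,a,s′) ← T(s,a,s′) + η δ_SPE` (other candidate rescaled by `1 − η`),
  then plans by backward induction under the goal-conditional reward
  `r(s) = R` at goal states, 0 otherwise:
  `Q_MB(s,a) = Σ_{s′} T(s,a,s′) { r(s′) + max_{a′} Q_MB(s′,a′) }`.
  Free parameters: `η`, `τ`.

Choice probabilities are softmax, `P(s,a) ∝ exp(τ Q(s,a))`; parameters are
estimated by minimizing the negative log-likelihood of the observed choices
with multi-restart (default 200) Nelder–Mead. From the fitted per-trial
likelihoods the package derives the dependent measures used to characterize
strategy: **MB preference** (% of trials where the MB likelihood exceeds the
MF likelihood), **system switching** (% of consecutive trials whose dominant
system changes), the **arbitration score** (MB preference ratio,
specific/flexible), plus **choice optimality** (% of trials whose two
decisions are optimal under the true task model) and **mean coins**. A
synthetic-agent module generates cohorts with known mixture weights so the
whole pipeline can be validated against ground truth, and a thin stats layer
provides the group-level ANOVA/ANCOVA, post-hoc contrasts, paired t-tests
and correlations.

## Worked example

```r
library(arbitrl)

tree     <- generate_tree(7)            # subject-specific decision tree
schedule <- generate_schedule(3)        # 56 blocks, ~280 trials
# an intact arbitrator: MB control on specific, MF control on flexible trials
agent    <- agent_spec("mixture", w_specific = 1, w_flexible = 0,
                       alpha = 0.4, tau_mf = 0.1, eta = 0.5, tau_mb = 0.1,
                       agent_seed = 11)
session  <- simulate_session(tree, schedule, agent)

fit_mf <- fit_learner(session, tree, "mf", n_restarts = 50, seed = 1)
fit_mb <- fit_learner(session, tree, "mb", n_restarts = 50, seed = 2)
print(fit_mf)
#> <fit_result> MF: rate = 0.457, tau = 0.04773, nll = 343.789 (50 restarts)
print(fit_mb)
#> <fit_result> MB: rate = 0.5004, tau = 0.07876, nll = 324.751 (50 restarts)

round(unlist(strategy_metrics(session, tree, fit_mf, fit_mb)[-1]), 2)
#>    mb_pref_specific    mb_pref_flexible     switch_specific     switch_flexible
#>               73.91               44.36               33.58               46.97
#> mean_coins_specific mean_coins_flexible optimality_specific optimality_flexible
#>               10.00               29.25               49.28               27.82
#>   arbitration_score
#>                1.67
```

Read-out: the MB fit explains this agent's choices better overall (lower
NLL), and the trial-resolved traces show why — the MB system dominates on
73.9% of specific trials but only 44.4% of flexible trials, an arbitration
score of 1.67: the agent deploys planning where the goal rule demands it.
The generating `η = 0.5` is recovered almost exactly (0.5004).

Cohort-level use mirrors the single subject:

```r
cohort  <- make_cohort(n_per_group = 20, master_seed = 42)  # intact vs impaired
cm      <- cohort_metrics(cohort, n_restarts = 20, seed = 7)
compare_groups(cm$metrics, "arbitration_score", "group")
paired_and_correlational(cm$metrics, "group")
```

A command-line wrapper with subcommands `gen-task`, `simulate`, `fit`,
`metrics`, `stats` and `run` is installed at
`system.file("cli", "arbitrl.R", package = "arbitrl")`, and
`run_pipeline()` executes simulate → fit → metrics → stats end-to-end into
an output directory with a reproducibility manifest.

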