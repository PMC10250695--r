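# Hand-built fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's backward-induction
# code paths: values are computed by exhaustive enumeration over paths /
# policies, or by generic value iteration run to convergence.

# Small fixed tree (1 root, 2 stage-2 states, 4 terminals: 0/10/20/40).
toy_tree <- function() {
  succ <- matrix(NA_integer_, nrow = 6L, ncol = 2L,
                 dimnames = list(NULL, c("likely", "unlikely")))
  succ[1L, ] <- c(1L, 2L)  # (0, left)
  succ[2L, ] <- c(2L, 1L)  # (0, right)
  succ[3L, ] <- c(3L, 4L)  # (1, left)
  succ[4L, ] <- c(4L, 5L)  # (1, right)
  succ[5L, ] <- c(5L, 6L)  # (2, left)
  succ[6L, ] <- c(6L, 3L)  # (2, right)
  structure(list(
    n2 = 2L, n3 = 4L, succ = succ,
    terminal_value = c(0, 10, 20, 40),
    terminal_color = c("gray", "yellow", "red", "blue"),
    tree_seed = 0L,
    config = tree_config(2L, 4L, c(0, 10, 20, 40))
  ), class = "decision_tree")
}

toy_rewards <- function(tree, condition, goal = NULL) {
  r <- tree$terminal_value
  if (condition == "specific") r[tree$terminal_color != goal] <- 0
  r
}
terminal_rewards_for_test <- toy_rewards

# Transition probability of landing on state `to` from (state, action)
# given a per-pair distribution matrix over (likely, unlikely).
trans_prob <- function(tree, Tmat, s, a, to) {
  row <- s * 2L + a + 1L
  cand <- tree$succ[row, ]
  p <- Tmat[row, ]
  sum(p[cand == to])
}

# Closed-loop brute force: enumerate every deterministic policy (root
# action plus one action per stage-2 state) and average rewards over all
# terminal paths. Returns the maximal expected reward at the root.
enumerate_policy_value <- function(tree, Tmat, r_term) {
  n2 <- tree$n2
  best <- -Inf
  for (combo in seq_len(2L^(n2 + 1L))) {
    idx <- (combo - 1L)
    acts <- integer(n2 + 1L)
    for (j in seq_len(n2 + 1L)) {
      acts[j] <- idx %% 2L
      idx <- idx %/% 2L
    }
    a1 <- acts[1L]
    ev <- 0
    for (s2 in seq_len(n2)) {
      p1 <- trans_prob(tree, Tmat, 0L, a1, s2)
      if (p1 == 0) next
      a2 <- acts[1L + s2]
      for (s3 in (n2 + 1L):(n2 + tree$n3)) {
        p2 <- trans_prob(tree, Tmat, s2, a2, s3)
        if (p2 > 0) ev <- ev + p1 * p2 * r_term[s3 - n2]
      }
    }
    best <- max(best, ev)
  }
  best
}

# Open-loop variant: the 4 fixed action sequences (a1, a2) applied
# regardless of the realized stage-2 state.
enumerate_sequence_values <- function(tree, Tmat, r_term) {
  n2 <- tree$n2
  vals <- matrix(NA_real_, 2L, 2L, dimnames = list(a1 = 0:1, a2 = 0:1))
  for (a1 in 0:1) {
    for (a2 in 0:1) {
      ev <- 0
      for (s2 in seq_len(n2)) {
        p1 <- trans_prob(tree, Tmat, 0L, a1, s2)
        if (p1 == 0) next
        for (s3 in (n2 + 1L):(n2 + tree$n3)) {
          p2 <- trans_prob(tree, Tmat, s2, a2, s3)
          if (p2 > 0) ev <- ev + p1 * p2 * r_term[s3 - n2]
        }
      }
      vals[a1 + 1L, a2 + 1L] <- ev
    }
  }
  vals
}

# Generic value iteration to convergence on the (tree, T, rewards) MDP;
# independent of the package's single-sweep backward induction.
value_iteration_oracle <- function(tree, Tmat, r_term, tol = 1e-12) {
  n2 <- tree$n2
  Q <- matrix(0, n2 + 1L, 2L)
  state_value <- function(Q, s) {
    if (s > n2) 0 else max(Q[s + 1L, ])
  }
  reward_of <- function(s) if (s > n2) r_term[s - n2] else 0
  repeat {
    Qn <- Q
    for (s in 0:n2) {
      for (a in 0:1) {
        row <- s * 2L + a + 1L
        cand <- tree$succ[row, ]
        Qn[s + 1L, a + 1L] <- sum(Tmat[row, ] *
                                    (vapply(cand, reward_of, 0) +
                                       vapply(cand, state_value, 0, Q = Q)))
      }
    }
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
}

# True transition matrix in the per-pair (likely, unlikely) layout.
true_T <- function(tree, uncertainty) {
  p <- if (uncertainty == "low") c(0.9, 0.1) else c(0.5, 0.5)
  matrix(rep(p, each = 2L * (tree$n2 + 1L)), ncol = 2L)
}

random_T <- function(tree) {
  n <- 2L * (tree$n2 + 1L)
  p <- runif(n)
  cbind(p, 1 - p)
}

# Minimal single-trial session data.frame.
one_trial_session <- function(tree, s2, a1, a2, s3, condition = "flexible",
                              goal = NA_character_, uncertainty = "low") {
  coins <- tree$terminal_value[s3 - tree$n2]
  paid <- if (condition == "flexible" ||
              tree$terminal_color[s3 - tree$n2] == goal) coins else 0
  data.frame(subject_id = "t", trial_index = 1L, block_index = 1L,
             phase = "main", condition = condition,
             uncertainty = uncertainty, goal_color = goal, s1 = 0L, a1 = a1,
             s2 = s2, a2 = a2, s3 = s3, coins_shown = coins,
             reward_paid = paid, missing = FALSE, stringsAsFactors = FALSE)
}

# Standard simulated session used by several tests.
sim_fixture <- function(agent_kind = "pure_mb", tree_seed = 7L,
                        schedule_seed = 3L, agent_seed = 11L, ...) {
  tree <- generate_tree(tree_seed)
  schedule <- generate_schedule(schedule_seed)
  agent <- agent_spec(agent_kind, agent_seed = agent_seed, ...)
  list(tree = tree, schedule = schedule, agent = agent,
       session = simulate_session(tree, schedule, agent))
}
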