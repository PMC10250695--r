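#' Model-free SARSA learner state
#'
#' Caches action values `Q_MF(s, a)` for every choice state, updated by
#' reward prediction errors. The discount factor is fixed at 1 and is not a
#' free parameter; the free parameters are the learning rate `alpha` and
#' the softmax inverse temperature `tau`.
#'
#' @param alpha Learning rate in (0, 1).
#' @param tau Inverse temperature, > 0 (0 allowed for a uniform policy).
#' @param tree A `decision_tree` (sets the Q-table dimensions).
#' @return Object of class `mf_state` with zero-initialized `Q`
#'   (rows = choice states 0..n2, columns = actions left/right).
#' @export
mf_state <- function(alpha, tau, tree) {
  check_rate(alpha, "alpha")
  check_tau(tau)
  structure(list(
    Q = matrix(0, nrow = tree$n2 + 1L, ncol = 2L),
    alpha = alpha, gamma = 1, tau = tau
  ), class = "mf_state")
}

#' Model-based learner state
#'
#' Holds the learned state-transition matrix `T(s, a, s')` (support
#' restricted to the two candidate successors of each pair, initialized
#' uniform) and the planned action values `Q_MB` produced by
#' [backward_plan()]. Free parameters: transition learning rate `eta` and
#' softmax inverse temperature `tau`.
#'
#' @param eta Transition learning rate in (0, 1).
#' @param tau Inverse temperature, > 0 (0 allowed for a uniform policy).
#' @param tree A `decision_tree`.
#' @return Object of class `mb_state` with `T` (one row per (state,
#'   action) pair, columns = the likely/unlikely candidates) and `Q`.
#' @export
mb_state <- function(eta, tau, tree) {
  check_rate(eta, "eta")
  check_tau(tau)
  n_pairs <- 2L * (tree$n2 + 1L)
  structure(list(
    T = matrix(0.5, nrow = n_pairs, ncol = 2L),
    Q = matrix(0, nrow = tree$n2 + 1L, ncol = 2L),
    eta = eta, tau = tau
  ), class = "mb_state")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
    stop(name, " must be in (0, 1)")
  }
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("tau must be >= 0")
  }
}

#' SARSA update from a reward prediction error
#'
#' `delta_RPE = r + gamma * Q(s', a') - Q(s, a)`; `Q(s, a) += alpha *
#' delta_RPE`. The reward is 0 on the stage-1 to stage-2 transition and
#' the paid (goal-gated) coins on the terminal transition; the bootstrap
#' term `Q(s', a')` is 0 at terminals (pass `a_next = NA`).
#'
#' @param mf An `mf_state`.
#' @param tree A `decision_tree`.
#' @param s,a Current state and chosen action.
#' @param s_next Observed successor state.
#' @param a_next Action subsequently chosen in `s_next`, or `NA` when
#'   `s_next` is terminal.
#' @param reward Reward experienced on this transition.
#' @return The updated `mf_state`.
#' @export
mf_update <- function(mf, tree, s, a, s_next, a_next, reward) {
  boot <- if (is_terminal(tree, s_next)) {
    0
  } else {
    if (is.na(a_next)) stop("a_next required for non-terminal s_next")
    mf$Q[s_next + 1L, a_next + 1L]
  }
  delta <- reward + mf$gamma * boot - mf$Q[s + 1L, a + 1L]
  mf$Q[s + 1L, a + 1L] <- mf$Q[s + 1L, a + 1L] + mf$alpha * delta
  mf
}

#' Transition-matrix update from a state prediction error
#'
#' After observing the transition `(s, a) -> s'`, the surprise is
#' `delta_SPE = 1 - T(s, a, s')` and the observed entry moves
#' `T(s, a, s') += eta * delta_SPE`. The non-observed candidate successor
#' is rescaled by `(1 - eta)` so the row remains a probability
#' distribution over the candidate successors.
#'
#' @param mb An `mb_state`.
#' @param tree A `decision_tree`.
#' @param s,a Non-terminal state and action taken.
#' @param s_next Observed successor; must be one of the two candidates.
#' @return The updated `mb_state`.
#' @export
mb_spe_update <- function(mb, tree, s, a, s_next) {
  row <- pair_index(s, a)
  cand <- tree$succ[row, ]
  j <- match(s_next, cand)
  if (is.na(j)) {
    stop("state ", s_next, " is not a candidate successor of (",
         s, ", ", a, ")")
  }
  t_row <- mb$T[row, ] * (1 - mb$eta)
  t_row[j] <- t_row[j] + mb$eta          # equals T + eta * (1 - T)
  mb$T[row, ] <- t_row
  mb
}

#' Backward planning over the learned transition model
#'
#' Sets the goal-conditional terminal rewards (`r(s') = coins` for goal
#' states, 0 otherwise; in the flexible condition every colored coin is a
#' goal state) and then sweeps the tree backward over stages 3 and 2,
#' computing `Q_MB(s, a) = sum_s' T(s, a, s') * (r(s') + max_a' Q_MB(s',
#' a'))` with the max defined as 0 at terminals. Rerun at the start of
#' every trial because the goal changes across trials.
#'
#' @param mb An `mb_state`.
#' @param tree A `decision_tree`.
#' @param condition `"specific"` or `"flexible"`.
#' @param goal_color Goal color for the specific condition.
#' @return The `mb_state` with `Q` refreshed.
#' @export
backward_plan <- function(mb, tree, condition, goal_color = NULL) {
  r_term <- terminal_rewards(tree, condition, goal_color)
  n2 <- tree$n2
  Q <- matrix(0, nrow = n2 + 1L, ncol = 2L)
  for (s in seq_len(n2)) {
    for (a in 0:1) {
      row <- pair_index(s, a)
      cand <- tree$succ[row, ]
      Q[s + 1L, a + 1L] <- sum(mb$T[row, ] * r_term[cand - n2])
    }
  }
  v2 <- apply(Q[-1L, , drop = FALSE], 1L, max)
  for (a in 0:1) {
    row <- pair_index(0L, a)
    cand <- tree$succ[row, ]
    Q[1L, a + 1L] <- sum(mb$T[row, ] * v2[cand])
  }
  mb$Q <- Q
  mb
}

#' Softmax choice probabilities
#'
#' `P(a) = exp(tau * Q_a) / sum_b exp(tau * Q_b)`, computed with
#' max-subtraction for overflow safety. `tau = 0` gives the uniform
#' policy.
#'
#' @param q Numeric vector of action values at one state.
#' @param tau Inverse temperature, >= 0.
#' @return Probability vector of the same length, summing to 1.
#' @export
softmax_prob <- function(q, tau) {
  check_tau(tau)
  z <- tau * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
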