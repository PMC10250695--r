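#' Tree topology configuration
#'
#' Describes the shape of a subject-specific decision tree: the number of
#' stage-2 and stage-3 (terminal) states and the multiset of coin values
#' placed on the terminals. Coin values map to colors as 0 = gray,
#' 10 = yellow, 20 = red, 40 = blue.
#'
#' @param n2 Number of stage-2 states.
#' @param n3 Number of terminal (stage-3) states.
#' @param terminal_values Numeric vector of length `n3` giving the coin
#'   values to distribute over the terminals. Must contain at least one of
#'   each rewarded value (10, 20, 40) so that every specific goal color is
#'   attainable.
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(n2 = 4L, n3 = 8L,
                        terminal_values = rep(c(0, 10, 20, 40), length.out = n3)) {
  n2 <- as.integer(n2)
  n3 <- as.integer(n3)
  if (n2 < 2L) stop("n2 must be >= 2")
  if (n3 < 2L) stop("n3 must be >= 2")
  if (length(terminal_values) != n3) {
    stop("terminal_values must have length n3")
  }
  if (!all(terminal_values %in% c(0, 10, 20, 40))) {
    stop("terminal coin values must be in {0, 10, 20, 40}")
  }
  missing_col <- setdiff(c(10, 20, 40), terminal_values)
  if (length(missing_col) > 0) {
    stop("terminal_values must include every rewarded value (10, 20, 40); ",
         "missing: ", paste(missing_col, collapse = ", "),
         " (a specific goal would be unattainable)")
  }
  structure(list(n2 = n2, n3 = n3, terminal_values = as.numeric(terminal_values)),
            class = "tree_config")
}

# (state, action) -> row index into the successor matrix. States are 0-based
# ids (0 = root, 1..n2 = stage 2); actions are 0 = left, 1 = right.
pair_index <- function(state, action) state * 2L + action + 1L

#' Generate a subject-specific decision tree
#'
#' Builds the 2-choice, 3-stage task graph: a single root state, `n2`
#' stage-2 states and `n3` terminal states carrying colored coins. Every
#' (state, action) pair in stages 1-2 has exactly two candidate successor
#' states in the next stage; which of the two is the "likely" successor
#' under low transition uncertainty is fixed at generation time. Trees are
#' resampled until every rewarded coin color (yellow, red, blue) is
#' reachable from the root, so any specific goal is attainable.
#'
#' States are 0-based integers grouped by stage: 0 is the root, 1..n2 the
#' stage-2 states, (n2+1)..(n2+n3) the terminals. Actions are coded
#' 0 = left, 1 = right.
#'
#' @param tree_seed Integer seed; identical seed and config give an
#'   identical tree.
#' @param config A [tree_config()].
#' @return An object of class `decision_tree` with elements `n2`, `n3`,
#'   `succ` (integer matrix, one row per (state, action) pair, columns
#'   `likely` and `unlikely` holding candidate successor state ids),
#'   `terminal_value`, `terminal_color` (indexed by `state - n2`),
#'   `tree_seed` and `config`.
#' @export
generate_tree <- function(tree_seed, config = tree_config()) {
  stopifnot(inherits(config, "tree_config"))
  with_seed(as.integer(tree_seed), {
    for (attempt in seq_len(1000L)) {
      tree <- sample_tree_once(tree_seed, config)
      if (all(REWARD_COLORS %in% reachable_colors(tree))) {
        return(tree)
      }
    }
  })
  stop("failed to generate a tree with all goal colors reachable")
}

sample_tree_once <- function(tree_seed, config) {
  n2 <- config$n2
  n3 <- config$n3
  n_choice <- 1L + n2
  succ <- matrix(NA_integer_, nrow = 2L * n_choice, ncol = 2L,
                 dimnames = list(NULL, c("likely", "unlikely")))
  stage2 <- seq_len(n2)                 # ids 1..n2
  stage3 <- n2 + seq_len(n3)            # ids n2+1..n2+n3
  for (a in 0:1) {
    succ[pair_index(0L, a), ] <- sample(stage2, 2L)
  }
  for (s in stage2) {
    for (a in 0:1) {
      succ[pair_index(s, a), ] <- sample(stage3, 2L)
    }
  }
  values <- sample(config$terminal_values)
  structure(list(
    n2 = n2, n3 = n3, succ = succ,
    terminal_value = values,
    terminal_color = unname(COIN_COLORS[as.character(values)]),
    tree_seed = as.integer(tree_seed),
    config = config
  ), class = "decision_tree")
}

# Coin colors reachable from the root through candidate transitions.
reachable_colors <- function(tree) {
  s2 <- unique(as.vector(tree$succ[pair_index(0L, 0:1), ]))
  s3 <- unique(as.vector(tree$succ[pair_index(rep(s2, each = 2L), 0:1), ]))
  unique(tree$terminal_color[s3 - tree$n2])
}

is_terminal <- function(tree, state) state > tree$n2

#' @export
print.decision_tree <- function(x, ...) {
  cat("<decision_tree> 1-", x$n2, "-", x$n3, " states, seed ", x$tree_seed,
      "\n", sep = "")
  cat("terminals:",
      paste0(x$n2 + seq_len(x$n3), "=", x$terminal_value,
             "(", x$terminal_color, ")", collapse = " "), "\n")
  invisible(x)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  n2 <- tree$n2; n3 <- tree$n3
  for (s in 0:n2) {
    next_stage <- if (s == 0L) seq_len(n2) else n2 + seq_len(n3)
    for (a in 0:1) {
      cand <- tree$succ[pair_index(s, a), ]
      if (anyNA(cand) || length(unique(cand)) != 2L ||
          !all(cand %in% next_stage)) {
        stop("invalid successors for state ", s, " action ", a)
      }
    }
  }
  ok <- tree$terminal_color == unname(COIN_COLORS[as.character(tree$terminal_value)])
  if (!all(ok)) stop("terminal value/color mismatch")
  if (!all(REWARD_COLORS %in% reachable_colors(tree))) {
    stop("not every goal color is reachable from the root")
  }
  invisible(tree)
}

#' Generate a session block schedule
#'
#' The main phase interleaves four block types: (specific, flexible)
#' conditions crossed with (low, high) state-transition uncertainty. There
#' are `blocks_per_type` (default 14) blocks of each type, randomly
#' ordered, for 56 blocks in total. Low-uncertainty blocks run 3-5 trials,
#' high-uncertainty blocks 5-7 trials (uniform within range), which makes
#' the expected session length 280 trials. Each specific block carries a
#' goal color drawn uniformly from yellow/red/blue.
#'
#' With `training = TRUE` the schedule is preceded by a training phase of
#' 80 flexible trials followed by 20 specific trials (goal color drawn per
#' trial), represented as single-trial blocks with negative `block_index`.
#' Training trials are excluded from fitting and metrics downstream.
#'
#' @param schedule_seed Integer seed.
#' @param blocks_per_type Blocks per (condition, uncertainty) type.
#' @param low_trials,high_trials Integer ranges for per-block trial counts.
#' @param training Prepend the training phase?
#' @return Object of class `session_schedule`: a data.frame of blocks with
#'   columns `phase`, `block_index`, `condition`, `uncertainty`,
#'   `goal_color`, `n_trials`, plus attribute `schedule_seed`.
#' @export
generate_schedule <- function(schedule_seed, blocks_per_type = 14L,
                              low_trials = 3:5, high_trials = 5:7,
                              training = FALSE) {
  with_seed(as.integer(schedule_seed), {
    types <- expand.grid(condition = c("specific", "flexible"),
                         uncertainty = c("low", "high"),
                         stringsAsFactors = FALSE)
    main <- types[rep(seq_len(nrow(types)), each = blocks_per_type), ]
    main <- main[sample.int(nrow(main)), ]
    main$phase <- "main"
    main$block_index <- seq_len(nrow(main))
    main$n_trials <- ifelse(main$uncertainty == "low",
                            sample(low_trials, nrow(main), replace = TRUE),
                            sample(high_trials, nrow(main), replace = TRUE))
    main$goal_color <- ifelse(main$condition == "specific",
                              sample(REWARD_COLORS, nrow(main), replace = TRUE),
                              NA_character_)
    blocks <- main
    if (training) {
      n_tr <- 80L + 20L
      tr <- data.frame(
        condition = rep(c("flexible", "specific"), c(80L, 20L)),
        uncertainty = sample(c("low", "high"), n_tr, replace = TRUE),
        phase = "training",
        block_index = -(n_tr:1L),
        n_trials = 1L,
        stringsAsFactors = FALSE
      )
      tr$goal_color <- ifelse(tr$condition == "specific",
                              sample(REWARD_COLORS, n_tr, replace = TRUE),
                              NA_character_)
      blocks <- rbind(tr[names(main)], main)
    }
    blocks <- blocks[, c("phase", "block_index", "condition", "uncertainty",
                         "goal_color", "n_trials")]
    rownames(blocks) <- NULL
    structure(blocks, schedule_seed = as.integer(schedule_seed),
              class = c("session_schedule", "data.frame"))
  })
}

# True transition probabilities over (likely, unlikely) candidates.
transition_probs <- function(uncertainty) {
  switch(match.arg(uncertainty, c("low", "high")),
         low = c(0.9, 0.1),
         high = c(0.5, 0.5))
}

#' Sample a probabilistic state transition
#'
#' Moves from a non-terminal state under the chosen action: the likely
#' candidate successor is reached with probability 0.9 under low
#' uncertainty and 0.5 under high uncertainty, otherwise the unlikely one.
#' Uses the current R random number generator; seed with [set.seed()].
#'
#' @param tree A `decision_tree`.
#' @param state Non-terminal state id.
#' @param action Action code (0 = left, 1 = right).
#' @param uncertainty `"low"` or `"high"`.
#' @param n Number of independent draws.
#' @return Integer vector of `n` successor state ids.
#' @export
sample_transition <- function(tree, state, action, uncertainty, n = 1L) {
  if (is_terminal(tree, state)) {
    stop("state ", state, " is terminal; no transitions available")
  }
  stopifnot(action %in% c(0L, 1L))
  p <- transition_probs(uncertainty)
  cand <- tree$succ[pair_index(as.integer(state), as.integer(action)), ]
  cand[1L + (runif(n) >= p[1L])]
}

# Goal-gated terminal rewards: in the flexible condition every coin pays
# its face value; in the specific condition only the goal color pays.
terminal_rewards <- function(tree, condition, goal_color = NULL) {
  condition <- match.arg(condition, c("specific", "flexible"))
  r <- tree$terminal_value
  if (condition == "specific") {
    if (is.null(goal_color) || !(goal_color %in% REWARD_COLORS)) {
      stop("specific condition requires goal_color in yellow/red/blue")
    }
    r <- ifelse(tree$terminal_color == goal_color, r, 0)
  }
  r
}

#' Optimal policy and state-action values under the true task model
#'
#' Backward induction on the true transition probabilities and the
#' goal-conditional reward rule. Returns the expected-reward-maximizing
#' action set at every choice state; ties (within `tol`) return both
#' actions. This is the oracle against which choice optimality is scored.
#'
#' @param tree A `decision_tree`.
#' @param condition `"specific"` or `"flexible"`.
#' @param goal_color Goal color for the specific condition.
#' @param uncertainty `"low"` or `"high"`.
#' @param tol Tie tolerance on expected values.
#' @return A list with `Q` (matrix of expected rewards, one row per choice
#'   state 0..n2, columns = actions), `root_value`, and `optimal` (list of
#'   optimal action sets, element `s + 1` for state `s`).
#' @export
optimal_policy_value <- function(tree, condition, goal_color = NULL,
                                 uncertainty, tol = 1e-9) {
  p <- transition_probs(uncertainty)
  r_term <- terminal_rewards(tree, condition, goal_color)
  n2 <- tree$n2
  Q <- matrix(0, nrow = n2 + 1L, ncol = 2L)
  for (s in seq_len(n2)) {         # stage-2 states: expectation over coins
    for (a in 0:1) {
      cand <- tree$succ[pair_index(s, a), ]
      Q[s + 1L, a + 1L] <- sum(p * r_term[cand - n2])
    }
  }
  v2 <- apply(Q[-1L, , drop = FALSE], 1L, max)   # value of each stage-2 state
  for (a in 0:1) {
    cand <- tree$succ[pair_index(0L, a), ]
    Q[1L, a + 1L] <- sum(p * v2[cand])
  }
  optimal <- lapply(seq_len(n2 + 1L), function(i) {
    which(Q[i, ] >= max(Q[i, ]) - tol) - 1L
  })
  list(Q = Q, root_value = max(Q[1L, ]), optimal = optimal,
       condition = condition, goal_color = goal_color,
       uncertainty = uncertainty)
}
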