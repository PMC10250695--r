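test_that("generated trees satisfy the structural invariants", {
  tree <- generate_tree(1)
  expect_s3_class(tree, "decision_tree")
  # default 1-4-8 topology: (1 + 4) choice states x 2 actions = 10 pairs,
  # each with exactly 2 distinct candidate successors in the next stage
  expect_equal(nrow(tree$succ), 10L)
  for (s in 0:tree$n2) {
    next_stage <- if (s == 0L) 1:4 else 5:12
    for (a in 0:1) {
      cand <- tree$succ[s * 2L + a + 1L, ]
      expect_length(unique(cand), 2L)
      expect_true(all(cand %in% next_stage))
    }
  }
  # value <-> color pairing and the full label multiset
  expect_equal(sort(tree$terminal_value), rep(c(0, 10, 20, 40), each = 2))
  expect_equal(tree$terminal_color,
               c(`0` = "gray", `10` = "yellow", `20` = "red",
                 `40` = "blue")[as.character(tree$terminal_value)],
               ignore_attr = TRUE)
  # every rewarded color reachable from the root (specific goals attainable)
  for (seed in 1:25) {
    expect_no_error(arbitrl:::validate_tree(generate_tree(seed)))
  }
})

test_that("tree generation is deterministic and rejects bad configs", {
  expect_identical(generate_tree(42), generate_tree(42))
  expect_false(identical(generate_tree(42)$succ, generate_tree(43)$succ))
  # a label multiset lacking a rewarded color is rejected up front
  expect_error(tree_config(4, 8, c(0, 0, 10, 10, 20, 20, 0, 10)),
               "missing: 40")
  expect_error(tree_config(4, 8, c(0, 10, 20, 40, 5, 0, 10, 20)),
               "coin values")
})

test_that("schedules have 56 blocks, 14 per type, lengths in range", {
  for (seed in c(1, 2, 99)) {
    sch <- generate_schedule(seed)
    expect_equal(nrow(sch), 56L)
    expect_equal(unname(table(sch$condition, sch$uncertainty)),
                 matrix(14L, 2, 2), ignore_attr = TRUE)
    expect_true(all(sch$n_trials[sch$uncertainty == "low"] %in% 3:5))
    expect_true(all(sch$n_trials[sch$uncertainty == "high"] %in% 5:7))
    expect_true(all(sch$goal_color[sch$condition == "specific"] %in%
                      c("yellow", "red", "blue")))
    expect_true(all(is.na(sch$goal_color[sch$condition == "flexible"])))
  }
  expect_identical(generate_schedule(5), generate_schedule(5))
})

test_that("expected session length is 280 trials", {
  totals <- vapply(1:200, function(s) sum(generate_schedule(s)$n_trials),
                   numeric(1))
  # E[total] = 28 blocks * 4 + 28 blocks * 6 = 280
  expect_lt(abs(mean(totals) - 280), 2)
})

test_that("training phase adds 80 flexible then 20 specific trials", {
  sch <- generate_schedule(1, training = TRUE)
  tr <- sch[sch$phase == "training", ]
  expect_equal(nrow(sch[sch$phase == "main", ]), 56L)
  expect_equal(sum(tr$n_trials[tr$condition == "flexible"]), 80L)
  expect_equal(sum(tr$n_trials[tr$condition == "specific"]), 20L)
  expect_true(all(tr$block_index < 1L))
  # flexible training precedes specific training
  expect_true(max(which(tr$condition == "flexible")) <
                min(which(tr$condition == "specific")))
})

test_that("transition sampling matches the stated probabilities", {
  tree <- generate_tree(3)
  set.seed(42)
  draws_low <- sample_transition(tree, 0L, 0L, "low", n = 10000L)
  draws_high <- sample_transition(tree, 0L, 1L, "high", n = 10000L)
  cand_low <- tree$succ[1L, ]
  cand_high <- tree$succ[2L, ]
  expect_true(all(draws_low %in% cand_low))
  f_low <- mean(draws_low == cand_low[["likely"]])
  f_high <- mean(draws_high == cand_high[["likely"]])
  expect_lt(abs(f_low - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
  expect_lt(abs(f_high - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(sample_transition(tree, tree$n2 + 1L, 0L, "low"), "terminal")
})

test_that("optimal policy on the toy tree follows the single 40-coin path", {
  tree <- toy_tree()
  # blue (40) sits on terminal 6, the likely successor of (2, right);
  # state 2 is the likely successor of (0, right)
  o <- optimal_policy_value(tree, "specific", "blue", "low")
  expect_equal(o$optimal[[1L]], 1L)  # root: right
  expect_equal(o$optimal[[3L]], 1L)  # state 2: right
  # exhaustive check against the closed-loop enumeration oracle
  r <- toy_rewards(tree, "specific", "blue")
  expect_equal(o$root_value,
               enumerate_policy_value(tree, true_T(tree, "low"), r),
               tolerance = 1e-12)
})

test_that("optimal policy handles bounds and ties", {
  tree <- toy_tree()
  # yellow labels only the 10-coin terminal: root value cannot exceed 10
  o <- optimal_policy_value(tree, "specific", "yellow", "low")
  expect_lte(o$root_value, 10)
  # all-equal terminals: every action ties as optimal
  eq_tree <- toy_tree()
  eq_tree$terminal_value <- rep(10, 4)
  eq_tree$terminal_color <- rep("yellow", 4)
  o_eq <- optimal_policy_value(eq_tree, "flexible", NULL, "high")
  for (s in 1:3) expect_equal(o_eq$optimal[[s]], c(0L, 1L))
})

test_that("backward induction equals brute-force policy enumeration on random trees", {
  set.seed(101)
  for (i in 1:20) {
    tree <- generate_tree(i + 300)
    for (unc in c("low", "high")) {
      for (cond in list(c("flexible", NA), c("specific", "red"),
                        c("specific", "blue"))) {
        goal <- if (cond[1] == "specific") cond[2] else NULL
        o <- optimal_policy_value(tree, cond[1], goal, unc)
        r <- terminal_rewards_for_test(tree, cond[1], goal)
        expect_equal(o$root_value,
                     enumerate_policy_value(tree, true_T(tree, unc), r),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("goal-gated payouts never exceed the shown coins", {
  fx <- sim_fixture("mixture", w = 0.5, missing_rate = 0)
  s <- fx$session
  expect_true(all(s$reward_paid <= s$coins_shown))
  flex <- s$condition == "flexible"
  expect_equal(s$reward_paid[flex], s$coins_shown[flex])
  spec <- s$condition == "specific"
  hit <- fx$tree$terminal_color[s$s3[spec] - fx$tree$n2] == s$goal_color[spec]
  expect_equal(s$reward_paid[spec], ifelse(hit, s$coins_shown[spec], 0))
})
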