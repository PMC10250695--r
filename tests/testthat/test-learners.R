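test_that("SARSA update matches hand arithmetic", {
  tree <- toy_tree()
  mf <- mf_state(0.5, 0.1, tree)
  # zero Q, zero reward: no change
  mf0 <- mf_update(mf, tree, 0L, 0L, 1L, 0L, 0)
  expect_equal(mf0$Q, mf$Q)
  # terminal reward 40, alpha 0.5: Q jumps to 20 (bootstrap 0 at terminal)
  mf1 <- mf_update(mf, tree, 1L, 0L, 3L, NA, 40)
  expect_equal(mf1$Q[2L, 1L], 20)
  expect_equal(sum(mf1$Q != 0), 1L)  # no other entry changes
  expect_error(mf_state(1.5, 0.1, tree), "alpha")
  expect_error(mf_state(0, 0.1, tree), "alpha")
})

test_that("SARSA converges to the gamma = 1 fixed point on a fixed chain", {
  tree <- toy_tree()
  mf <- mf_state(0.3, 0.1, tree)
  # deterministic replay of the same 2-step path with constant reward 40
  for (i in 1:300) {
    mf <- mf_update(mf, tree, 0L, 1L, 2L, 0L, 0)
    mf <- mf_update(mf, tree, 2L, 0L, 5L, NA, 40)
  }
  expect_equal(mf$Q[3L, 1L], 40, tolerance = 1e-6)
  expect_equal(mf$Q[1L, 2L], 40, tolerance = 1e-6)
})

test_that("state-prediction-error update matches hand arithmetic and keeps rows on the simplex", {
  tree <- toy_tree()
  mb <- mb_state(0.2, 0.1, tree)
  # (0.5, 0.5), eta 0.2, observe the likely successor -> (0.6, 0.4)
  mb1 <- mb_spe_update(mb, tree, 0L, 0L, 1L)
  expect_equal(mb1$T[1L, ], c(0.6, 0.4), ignore_attr = TRUE)
  expect_equal(sum(mb1$T[1L, ]), 1)
  # absorbing case: T = 1 observed again stays put
  mb1$T[1L, ] <- c(1, 0)
  mb2 <- mb_spe_update(mb1, tree, 0L, 0L, 1L)
  expect_equal(mb2$T[1L, ], c(1, 0), ignore_attr = TRUE)
  expect_error(mb_spe_update(mb, tree, 0L, 0L, 5L), "not a candidate")
})

test_that("repeated observation drives T to 1 monotonically for any eta", {
  tree <- toy_tree()
  for (eta in c(0.05, 0.5, 0.95)) {
    mb <- mb_state(eta, 0.1, tree)
    t_prev <- mb$T[1L, 1L]
    for (i in 1:50) {
      mb <- mb_spe_update(mb, tree, 0L, 0L, 1L)
      expect_gte(mb$T[1L, 1L], t_prev)
      expect_equal(sum(mb$T[1L, ]), 1, tolerance = 1e-12)
      t_prev <- mb$T[1L, 1L]
    }
    expect_gt(mb$T[1L, 1L], 0.9)
  }
})

test_that("backward planning agrees with independent value iteration", {
  set.seed(7)
  # zero terminal rewards: all planned values zero
  mb <- mb_state(0.3, 0.1, toy_tree())
  tree_z <- toy_tree()
  tree_z$terminal_value <- rep(0, 4)
  expect_equal(backward_plan(mb, tree_z, "flexible")$Q,
               matrix(0, 3, 2))
  # learned (arbitrary) T on random trees vs value iteration to convergence
  for (i in 1:10) {
    tree <- generate_tree(i + 500)
    mb <- mb_state(0.4, 0.1, tree)
    mb$T <- random_T(tree)
    for (cond in list(c("flexible", NA), c("specific", "yellow"))) {
      goal <- if (cond[1] == "specific") cond[2] else NULL
      planned <- backward_plan(mb, tree, cond[1], goal)$Q
      vi <- value_iteration_oracle(tree, mb$T,
                                   terminal_rewards_for_test(tree, cond[1],
                                                             goal))
      expect_equal(planned, vi, tolerance = 1e-9)
    }
  }
})

test_that("planning on the true transition model recovers the optimal values", {
  for (seed in c(11, 12)) {
    tree <- generate_tree(seed + 700)
    for (unc in c("low", "high")) {
      mb <- mb_state(0.5, 0.1, tree)
      mb$T <- true_T(tree, unc)
      planned <- backward_plan(mb, tree, "flexible")
      oracle <- optimal_policy_value(tree, "flexible", NULL, unc)
      expect_equal(max(planned$Q[1L, ]), oracle$root_value,
                   tolerance = 1e-12)
    }
  }
})

test_that("softmax has the stated limits, closed form, and shift invariance", {
  expect_equal(softmax_prob(c(3, -1), 0), c(0.5, 0.5))
  expect_equal(softmax_prob(c(2, 2), 5), c(0.5, 0.5))
  expect_equal(softmax_prob(c(1, 0), 1),
               c(exp(1), 1) / (1 + exp(1)), tolerance = 1e-12)
  # overflow-safe at extreme values
  expect_equal(softmax_prob(c(1e6, 0), 10), c(1, 0))
  set.seed(1)
  for (i in 1:20) {
    q <- rnorm(2, sd = 10)
    tau <- runif(1, 0, 2)
    shift <- rnorm(1, sd = 100)
    expect_equal(softmax_prob(q, tau), softmax_prob(q + shift, tau),
                 tolerance = 1e-12)
    expect_equal(sum(softmax_prob(q, tau)), 1, tolerance = 1e-12)
  }
})

test_that("a planner with the true model beats a uniform-random chooser on specific trials", {
  set.seed(21)
  tree <- generate_tree(900)
  mb <- mb_state(0.5, 0.1, tree)
  mb$T <- true_T(tree, "low")
  reward_of <- function(pick_action) {
    total <- 0
    for (i in 1:1000) {
      goal <- sample(c("yellow", "red", "blue"), 1L)
      plan <- backward_plan(mb, tree, "specific", goal)
      s <- 0L
      for (stage in 1:2) {
        a <- pick_action(plan$Q[s + 1L, ])
        s <- sample_transition(tree, s, a, "low")
      }
      if (tree$terminal_color[s - tree$n2] == goal) {
        total <- total + tree$terminal_value[s - tree$n2]
      }
    }
    total / 1000
  }
  planner <- reward_of(function(q) which.max(q) - 1L)
  random <- reward_of(function(q) sample(0:1, 1L))
  expect_gt(planner, random)
})
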