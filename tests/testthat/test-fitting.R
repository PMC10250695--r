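test_that("uniform-policy closed form: tau = 0 gives nll = n_decisions * log 2", {
  fx <- sim_fixture("pure_mf", alpha = 0.3, tau_mf = 0.15)
  for (kind in c("mf", "mb")) {
    res <- session_nll(fx$session, fx$tree, kind, c(0.5, 0))
    expect_equal(res$nll, res$n_decisions * log(2), tolerance = 1e-12)
    expect_true(all(res$decision_prob == 0.5, na.rm = TRUE))
  }
})

test_that("single-trial likelihood matches hand arithmetic", {
  tree <- toy_tree()
  ses <- one_trial_session(tree, s2 = 1L, a1 = 0L, a2 = 1L, s3 = 4L)
  # naive learners: Q identically 0 at decision 1 -> p1 = 0.5;
  # MB plans from uniform T: Q2(s=1) = (0.5*0+0.5*10, 0.5*10+0.5*20) = (5, 15)
  tau <- 0.2
  p2_mb <- exp(tau * 15) / (exp(tau * 5) + exp(tau * 15))
  mb <- session_nll(ses, tree, "mb", c(0.3, tau))
  expect_equal(mb$decision_prob[1, ], c(0.5, p2_mb), tolerance = 1e-12)
  expect_equal(mb$nll, -log(0.5) - log(p2_mb), tolerance = 1e-12)
  # MF Q is all-zero throughout the first trial -> both decisions 0.5
  mf <- session_nll(ses, tree, "mf", c(0.3, tau))
  expect_equal(mf$nll, 2 * log(2), tolerance = 1e-12)
})

test_that("per-trial likelihood product equals exp(-nll) without missing trials", {
  fx <- sim_fixture("pure_mb", eta = 0.5, tau_mb = 0.1)
  res <- session_nll(fx$session, fx$tree, "mb", c(0.5, 0.1))
  expect_equal(sum(log(res$trial_likelihood)), -res$nll, tolerance = 1e-9)
})

test_that("C++ and R replay engines agree exactly", {
  fx <- sim_fixture("mixture", w = 0.6, missing_rate = 0.05,
                    lapse_rate = 0.05)
  for (kind in c("mf", "mb")) {
    for (params in list(c(0.2, 0.05), c(0.7, 0.3))) {
      a <- session_nll(fx$session, fx$tree, kind, params, engine = "cpp")
      b <- session_nll(fx$session, fx$tree, kind, params, engine = "r")
      expect_equal(a$nll, b$nll, tolerance = 1e-10)
      expect_equal(a$decision_prob, b$decision_prob, tolerance = 1e-12)
      expect_equal(a$trial_likelihood, b$trial_likelihood,
                   tolerance = 1e-12)
    }
  }
  # missing trials contribute no decisions
  miss <- fx$session$missing
  expect_true(any(miss))
  res <- session_nll(fx$session, fx$tree, "mf", c(0.3, 0.1))
  expect_true(all(is.na(res$trial_likelihood[miss])))
  expect_equal(res$n_decisions, 2L * sum(!miss))
})

test_that("session_nll rejects invalid inputs", {
  fx <- sim_fixture("pure_mf")
  expect_error(session_nll(fx$session, fx$tree, "mf", c(1.2, 0.1)), "alpha")
  expect_error(session_nll(fx$session, fx$tree, "mb", c(0.5, -1)), "tau")
  bad <- fx$session
  bad$s2[3] <- setdiff(1:4, fx$tree$succ[bad$a1[3] + 1L, ])[1L]
  expect_error(session_nll(bad, fx$tree, "mf", c(0.5, 0.1)), "row 3")
})

test_that("fitting is deterministic and restart sequences are nested", {
  fx <- sim_fixture("pure_mf", alpha = 0.3, tau_mf = 0.15)
  f1 <- fit_learner(fx$session, fx$tree, "mf", n_restarts = 6, seed = 9)
  f2 <- fit_learner(fx$session, fx$tree, "mf", n_restarts = 6, seed = 9)
  expect_identical(f1, f2)
  f3 <- fit_learner(fx$session, fx$tree, "mf", n_restarts = 3, seed = 9)
  expect_equal(f3$restart_nlls, f1$restart_nlls[1:3])
  expect_lte(f1$nll, f3$nll)            # best nll non-increasing in restarts
  expect_equal(f1$nll, min(f1$restart_nlls))
  expect_true(all(f1$per_trial_likelihood > 0 &
                    f1$per_trial_likelihood <= 1))
})

test_that("fitted nll is no worse than the generating parameters", {
  fx <- sim_fixture("pure_mb", eta = 0.5, tau_mb = 0.15)
  fit <- fit_learner(fx$session, fx$tree, "mb", n_restarts = 10, seed = 2)
  at_truth <- session_nll(fx$session, fx$tree, "mb", c(0.5, 0.15))$nll
  expect_lte(fit$nll, at_truth)
  expect_true(fit$converged)
  expect_gt(fit$params[["rate"]], 0)
  expect_lt(fit$params[["rate"]], 1)
})

test_that("generating parameters and system are recovered from simulated data", {
  # smoke-scale recovery (the acceptance suite runs the 20-replicate
  # version); 280-trial sessions from a pure-MF agent
  errs <- c()
  for (rep in 1:3) {
    fx <- sim_fixture("pure_mf", alpha = 0.3, tau_mf = 0.15,
                      tree_seed = 40 + rep, schedule_seed = 50 + rep,
                      agent_seed = 60 + rep)
    fmf <- fit_learner(fx$session, fx$tree, "mf", n_restarts = 10,
                       seed = rep)
    fmb <- fit_learner(fx$session, fx$tree, "mb", n_restarts = 10,
                       seed = rep + 100)
    expect_lt(fmf$nll, fmb$nll)
    errs <- c(errs, abs(fmf$params[["rate"]] - 0.3))
  }
  expect_lt(median(errs), 0.15)
})

test_that("recovery error shrinks with session length (280 vs 2,800 trials)", {
  err_at <- function(blocks_per_type) {
    errs <- vapply(1:3, function(rep) {
      tree <- generate_tree(70 + rep)
      sch <- generate_schedule(80 + rep, blocks_per_type = blocks_per_type)
      ag <- agent_spec("pure_mf", alpha = 0.3, tau_mf = 0.15,
                       agent_seed = 90 + rep)
      ses <- simulate_session(tree, sch, ag)
      fit <- fit_learner(ses, tree, "mf", n_restarts = 8, seed = rep)
      abs(fit$params[["rate"]] - 0.3)
    }, numeric(1))
    median(errs)
  }
  expect_lte(err_at(140L), err_at(14L) + 0.02)
})
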