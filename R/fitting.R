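COLOR_CODES <- c(gray = 0L, yellow = 1L, red = 2L, blue = 3L)

# Session data.frame -> integer matrix consumed by the C++ replay.
encode_session <- function(session, tree) {
  goal <- COLOR_CODES[session$goal_color]
  goal[is.na(goal)] <- 0L
  cbind(s1 = session$s1, a1 = session$a1, s2 = session$s2, a2 = session$a2,
        s3 = session$s3,
        specific = as.integer(session$condition == "specific"),
        goal = as.integer(goal),
        missing = as.integer(session$missing))
}

subset_phase <- function(session, phase) {
  phase <- match.arg(phase, c("main", "all"))
  if (phase == "main" && "phase" %in% names(session)) {
    session <- session[session$phase == "main", , drop = FALSE]
  } else if (phase == "main" && "block_index" %in% names(session)) {
    session <- session[session$block_index >= 1L, , drop = FALSE]
  }
  session
}

#' Negative log-likelihood of a session under one learning system
#'
#' Replays the session in chronological order: at each of the trial's two
#' decisions the softmax probability of the *chosen* action is computed
#' from the learner's current values, then the learner is updated with the
#' *observed* transition and reward. The learner trajectory depends only
#' on the data and the parameters, never on the optimizer. Missing trials
#' contribute no decisions and no updates. Decision probabilities are
#' floored at 1e-12 before taking logs.
#'
#' @param session Trial data.frame (see [simulate_session()] /
#'   [read_session()]).
#' @param tree The subject's `decision_tree`.
#' @param learner_kind `"mf"` or `"mb"`.
#' @param params Numeric `c(rate, tau)`: learning rate in (0,1) and
#'   inverse temperature >= 0.
#' @param engine `"cpp"` (fast path used by fitting) or `"r"` (reference
#'   implementation built from the exported learner primitives).
#' @param phase `"main"` (default; drops training trials) or `"all"`.
#' @param validate Check session transitions against the tree first.
#' @return List with `nll`, `decision_prob` (n x 2 matrix of chosen-action
#'   probabilities, NA for missing trials), `trial_likelihood` (product of
#'   the two decision probabilities per trial) and `n_decisions`.
#' @export
session_nll <- function(session, tree, learner_kind = c("mf", "mb"), params,
                        engine = c("cpp", "r"), phase = "main",
                        validate = TRUE) {
  learner_kind <- match.arg(learner_kind)
  engine <- match.arg(engine)
  rate <- params[[1L]]
  tau <- params[[2L]]
  check_rate(rate, if (learner_kind == "mf") "alpha" else "eta")
  check_tau(tau)
  session <- subset_phase(session, phase)
  if (nrow(session) == 0L) stop("session has no trials in phase")
  if (validate) validate_session(session, tree)
  res <- if (engine == "cpp") {
    cpp_session_nll(encode_session(session, tree),
                    as.numeric(session$reward_paid), tree$succ,
                    tree$terminal_value,
                    unname(COLOR_CODES[tree$terminal_color]),
                    tree$n2, tree$n3,
                    if (learner_kind == "mf") 0L else 1L, rate, tau)
  } else {
    replay_session_r(session, tree, learner_kind, rate, tau)
  }
  res$n_decisions <- 2L * sum(!session$missing)
  res
}

# Reference replay in plain R, built from the learner primitives.
replay_session_r <- function(session, tree, learner_kind, rate, tau) {
  n <- nrow(session)
  probs <- matrix(NA_real_, n, 2L)
  mf <- if (learner_kind == "mf") mf_state(rate, tau, tree) else NULL
  mb <- if (learner_kind == "mb") mb_state(rate, tau, tree) else NULL
  nll <- 0
  for (t in seq_len(n)) {
    tr <- session[t, ]
    if (tr$missing) next
    if (learner_kind == "mb") {
      mb <- backward_plan(mb, tree, tr$condition,
                          if (tr$condition == "specific") tr$goal_color)
      Q <- mb$Q
    } else {
      Q <- mf$Q
    }
    probs[t, 1L] <- softmax_prob(Q[tr$s1 + 1L, ], tau)[tr$a1 + 1L]
    probs[t, 2L] <- softmax_prob(Q[tr$s2 + 1L, ], tau)[tr$a2 + 1L]
    if (learner_kind == "mf") {
      mf <- mf_update(mf, tree, tr$s1, tr$a1, tr$s2, tr$a2, 0)
      mf <- mf_update(mf, tree, tr$s2, tr$a2, tr$s3, NA, tr$reward_paid)
    } else {
      mb <- mb_spe_update(mb, tree, tr$s1, tr$a1, tr$s2)
      mb <- mb_spe_update(mb, tree, tr$s2, tr$a2, tr$s3)
    }
    nll <- nll - sum(log(pmax(probs[t, ], 1e-12)))
  }
  list(nll = nll, decision_prob = probs,
       trial_likelihood = probs[, 1L] * probs[, 2L])
}

#' Maximum-likelihood fit of one learning system to one session
#'
#' Minimizes [session_nll()] over (learning rate, inverse temperature)
#' with the Nelder-Mead simplex in an unconstrained reparameterization
#' (logit for the rate, log for tau), restarted from `n_restarts` random
#' seed points: rate uniform on (0.01, 0.99), tau log-uniform on
#' (0.01, 10). Deterministic given `seed`.
#'
#' @param session Trial data.frame.
#' @param tree The subject's `decision_tree`.
#' @param learner_kind `"mf"` or `"mb"`.
#' @param n_restarts Number of random restarts (default 200).
#' @param seed Integer seed for the restart draws.
#' @param maxit Maximum simplex evaluations per restart.
#' @param reltol Simplex convergence tolerance.
#' @param engine Likelihood engine, `"cpp"` or `"r"`.
#' @param phase `"main"` or `"all"`.
#' @return Object of class `fit_result`: `learner_kind`, `params`
#'   (named `rate`, `tau`), `nll`, `n_restarts`, `restart_nlls`,
#'   `per_trial_likelihood`, `decision_prob`, `converged`, `n_trials`,
#'   `seed`.
#' @export
fit_learner <- function(session, tree, learner_kind = c("mf", "mb"),
                        n_restarts = 200L, seed = 1L, maxit = 2000L,
                        reltol = 1e-8, engine = c("cpp", "r"),
                        phase = "main") {
  learner_kind <- match.arg(learner_kind)
  engine <- match.arg(engine)
  session <- subset_phase(session, phase)
  if (sum(!session$missing) < 1L) stop("session has no non-missing trials")
  validate_session(session, tree)

  obj <- function(x) {
    session_nll(session, tree, learner_kind,
                c(stats::plogis(x[1L]), exp(x[2L])), engine = engine,
                phase = "all", validate = FALSE)$nll
  }
  # one (rate, tau) draw per restart, in restart order, so that restart
  # sequences are nested across different n_restarts under the same seed
  starts <- with_seed(as.integer(seed), {
    u <- matrix(runif(2L * n_restarts), ncol = 2L, byrow = TRUE)
    cbind(rate = 0.01 + 0.98 * u[, 1L],
          tau = exp(log(0.01) + u[, 2L] * (log(10) - log(0.01))))
  })
  best <- NULL
  restart_nlls <- numeric(n_restarts)
  any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    x0 <- c(stats::qlogis(starts[i, 1L]), log(starts[i, 2L]))
    opt <- optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    restart_nlls[i] <- opt$value
    any_conv <- any_conv || opt$convergence == 0L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  params <- c(rate = unname(stats::plogis(best$par[1L])),
              tau = unname(exp(best$par[2L])))
  final <- session_nll(session, tree, learner_kind, params, engine = engine,
                       phase = "all", validate = FALSE)
  structure(list(
    learner_kind = learner_kind, params = params, nll = final$nll,
    n_restarts = as.integer(n_restarts), restart_nlls = restart_nlls,
    per_trial_likelihood = final$trial_likelihood,
    decision_prob = final$decision_prob,
    converged = any_conv, n_trials = nrow(session), seed = as.integer(seed)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", toupper(x$learner_kind), ": rate = ",
      signif(x$params[["rate"]], 4), ", tau = ",
      signif(x$params[["tau"]], 4), ", nll = ", signif(x$nll, 6),
      " (", x$n_restarts, " restarts", if (!x$converged) ", NOT converged",
      ")\n", sep = "")
  invisible(x)
}
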