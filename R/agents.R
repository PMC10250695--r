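#' Synthetic agent specification
#'
#' Describes a simulated subject. Both learning systems always run and
#' learn from every experienced outcome; the mixture weight `w` is the
#' probability that a given *trial's* two decisions are driven by the
#' model-based policy (one system controls a whole trial, matching the
#' per-trial preference measure). `w` may be condition-dependent, which is
#' how arbitration ability is operationalized: an intact arbitrator has
#' `w_specific` near 1 and `w_flexible` near 0, an impaired one has the
#' two weights close together.
#'
#' @param kind `"mixture"`, `"pure_mf"` (w = 0), `"pure_mb"` (w = 1) or
#'   `"random"` (uniform choices, learners still updated).
#' @param alpha,tau_mf Model-free learning rate and inverse temperature.
#' @param eta,tau_mb Model-based (transition) learning rate and inverse
#'   temperature.
#' @param w Trial-level probability of model-based control.
#' @param w_specific,w_flexible Optional condition-dependent weights
#'   (override `w`).
#' @param lapse_rate Probability a decision is uniform-random.
#' @param missing_rate Probability a trial is a timeout (`missing`).
#' @param agent_seed Integer seed for the agent's choice/transition noise.
#' @return Object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("mixture", "pure_mf", "pure_mb", "random"),
                       alpha = 0.4, tau_mf = 0.1, eta = 0.5, tau_mb = 0.1,
                       w = 0.5, w_specific = NULL, w_flexible = NULL,
                       lapse_rate = 0, missing_rate = 0, agent_seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "pure_mf") w <- 0
  if (kind == "pure_mb") w <- 1
  for (x in c(w, w_specific, w_flexible, lapse_rate, missing_rate)) {
    if (!is.null(x) && (x < 0 || x > 1)) stop("probabilities must be in [0, 1]")
  }
  if (is.null(w_specific) != is.null(w_flexible)) {
    stop("supply both or neither of w_specific / w_flexible")
  }
  structure(list(kind = kind, alpha = alpha, tau_mf = tau_mf, eta = eta,
                 tau_mb = tau_mb, w = w, w_specific = w_specific,
                 w_flexible = w_flexible, lapse_rate = lapse_rate,
                 missing_rate = missing_rate,
                 agent_seed = as.integer(agent_seed)),
            class = "agent_spec")
}

#' Simulate a full behavioral session
#'
#' Runs both learners forward through the schedule. On each trial the
#' controlling system is drawn from the (condition-dependent) mixture
#' weight, actions are sampled from that system's softmax (or uniformly on
#' lapses / for a `random` agent), transitions are sampled from the true
#' task probabilities, the goal rule pays the reward, and *both* learners
#' are updated from the experienced outcomes. Fully reproducible from the
#' tree, schedule and agent seeds.
#'
#' @param tree A `decision_tree`.
#' @param schedule A `session_schedule`.
#' @param agent An [agent_spec()].
#' @param subject_id Identifier written into the trial log.
#' @return A session data.frame (one row per trial) with the standard
#'   columns `subject_id`, `trial_index`, `block_index`, `condition`,
#'   `uncertainty`, `goal_color`, `s1`, `a1`, `s2`, `a2`, `s3`,
#'   `coins_shown`, `reward_paid`, `missing`, plus `phase`; the per-trial
#'   controlling system is kept in `attr(, "controller")`.
#' @export
simulate_session <- function(tree, schedule, agent, subject_id = "s1") {
  stopifnot(inherits(agent, "agent_spec"))
  n_total <- sum(schedule$n_trials)
  mf <- mf_state(agent$alpha, agent$tau_mf, tree)
  mb <- mb_state(agent$eta, agent$tau_mb, tree)
  out <- vector("list", n_total)
  controller <- character(n_total)
  with_seed(agent$agent_seed, {
    trial <- 0L
    for (b in seq_len(nrow(schedule))) {
      blk <- schedule[b, ]
      goal <- if (blk$condition == "specific") blk$goal_color else NA_character_
      for (k in seq_len(blk$n_trials)) {
        trial <- trial + 1L
        if (runif(1) < agent$missing_rate) {
          out[[trial]] <- data.frame(
            subject_id = subject_id, trial_index = trial,
            block_index = blk$block_index, phase = blk$phase,
            condition = blk$condition, uncertainty = blk$uncertainty,
            goal_color = goal, s1 = 0L, a1 = NA_integer_, s2 = NA_integer_,
            a2 = NA_integer_, s3 = NA_integer_, coins_shown = NA_real_,
            reward_paid = 0, missing = TRUE, stringsAsFactors = FALSE)
          controller[trial] <- "none"
          next
        }
        w <- if (!is.null(agent$w_specific)) {
          if (blk$condition == "specific") agent$w_specific else agent$w_flexible
        } else {
          agent$w
        }
        ctl <- if (agent$kind == "random") {
          "random"
        } else if (runif(1) < w) "mb" else "mf"
        controller[trial] <- ctl
        mb <- backward_plan(mb, tree, blk$condition, goal)
        pick <- function(state) {
          if (ctl == "random" || runif(1) < agent$lapse_rate) {
            return(sample(0:1, 1L))
          }
          q <- if (ctl == "mb") mb$Q[state + 1L, ] else mf$Q[state + 1L, ]
          tau <- if (ctl == "mb") agent$tau_mb else agent$tau_mf
          sample(0:1, 1L, prob = softmax_prob(q, tau))
        }
        s1 <- 0L
        a1 <- pick(s1)
        s2 <- sample_transition(tree, s1, a1, blk$uncertainty)
        a2 <- pick(s2)
        s3 <- sample_transition(tree, s2, a2, blk$uncertainty)
        coins <- tree$terminal_value[s3 - tree$n2]
        paid <- if (blk$condition == "flexible" ||
                    tree$terminal_color[s3 - tree$n2] == goal) coins else 0
        mf <- mf_update(mf, tree, s1, a1, s2, a2, 0)
        mf <- mf_update(mf, tree, s2, a2, s3, NA, paid)
        mb <- mb_spe_update(mb, tree, s1, a1, s2)
        mb <- mb_spe_update(mb, tree, s2, a2, s3)
        out[[trial]] <- data.frame(
          subject_id = subject_id, trial_index = trial,
          block_index = blk$block_index, phase = blk$phase,
          condition = blk$condition, uncertainty = blk$uncertainty,
          goal_color = goal, s1 = s1, a1 = a1, s2 = s2, a2 = a2, s3 = s3,
          coins_shown = coins, reward_paid = paid, missing = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  })
  session <- do.call(rbind, out)
  rownames(session) <- NULL
  attr(session, "controller") <- controller
  session
}

#' Cohort group specification
#'
#' Parameter ranges from which each simulated subject's agent is drawn
#' (uniformly). Arbitration ability is encoded in how far apart the
#' specific and flexible mixture weights sit.
#'
#' @param w_specific,w_flexible Length-2 ranges for the condition-dependent
#'   model-based weights.
#' @param alpha,eta,tau Length-2 ranges for learning rates and inverse
#'   temperatures (one tau draw per system).
#' @param lapse_rate,missing_rate Scalars shared by the group.
#' @return A list of class `cohort_group`.
#' @export
cohort_group <- function(w_specific = c(0.85, 1), w_flexible = c(0, 0.15),
                         alpha = c(0.2, 0.6), eta = c(0.3, 0.7),
                         tau = c(0.05, 0.2), lapse_rate = 0.02,
                         missing_rate = 0.01) {
  structure(list(w_specific = w_specific, w_flexible = w_flexible,
                 alpha = alpha, eta = eta, tau = tau,
                 lapse_rate = lapse_rate, missing_rate = missing_rate),
            class = "cohort_group")
}

default_cohort_groups <- function() {
  list(intact = cohort_group(w_specific = c(0.85, 1), w_flexible = c(0, 0.15)),
       impaired = cohort_group(w_specific = c(0.55, 0.75),
                               w_flexible = c(0.25, 0.45)))
}

#' Simulate a cohort of synthetic subjects with known ground truth
#'
#' Each subject receives an individual decision tree and block schedule
#' (as in the task, where every subject has their own tree) and an agent
#' drawn from their group's parameter ranges. The default groups contrast
#' intact arbitration (model-based control deployed on specific trials,
#' model-free on flexible) with impaired arbitration (the two weights
#' pulled toward each other).
#'
#' @param n_per_group Subjects per group (the clinical cohorts this stands
#'   in for had ~30 per group).
#' @param groups Named list of [cohort_group()] specs.
#' @param master_seed Integer seed; the same seed reproduces the cohort
#'   exactly.
#' @param training Include the training phase in each schedule.
#' @return Object of class `cohort`: `subjects` (list of
#'   `list(subject_id, group, tree, schedule, session, agent)`) and
#'   `truth` (data.frame of the generating parameters per subject).
#' @export
make_cohort <- function(n_per_group = 30L, groups = default_cohort_groups(),
                        master_seed = 1L, training = FALSE) {
  stopifnot(n_per_group >= 2L, length(groups) >= 1L,
            !is.null(names(groups)))
  n_total <- n_per_group * length(groups)
  seeds <- with_seed(as.integer(master_seed),
                     matrix(sample.int(2147483646L, 3L * n_total),
                            ncol = 3L))
  draws <- with_seed(as.integer(master_seed) + 1L,
                     matrix(runif(6L * n_total), ncol = 6L))
  subjects <- vector("list", n_total)
  truth <- vector("list", n_total)
  i <- 0L
  for (g in names(groups)) {
    spec <- groups[[g]]
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      u <- draws[i, ]
      pick <- function(range, un) range[1L] + un * (range[2L] - range[1L])
      agent <- agent_spec(
        kind = "mixture",
        alpha = pick(spec$alpha, u[1L]), eta = pick(spec$eta, u[2L]),
        tau_mf = pick(spec$tau, u[3L]), tau_mb = pick(spec$tau, u[4L]),
        w_specific = pick(spec$w_specific, u[5L]),
        w_flexible = pick(spec$w_flexible, u[6L]),
        lapse_rate = spec$lapse_rate, missing_rate = spec$missing_rate,
        agent_seed = seeds[i, 3L])
      id <- sprintf("%s_%02d", g, k)
      tree <- generate_tree(seeds[i, 1L])
      schedule <- generate_schedule(seeds[i, 2L], training = training)
      session <- simulate_session(tree, schedule, agent, subject_id = id)
      subjects[[i]] <- list(subject_id = id, group = g, tree = tree,
                            schedule = schedule, session = session,
                            agent = agent)
      truth[[i]] <- data.frame(
        subject_id = id, group = g, alpha = agent$alpha, eta = agent$eta,
        tau_mf = agent$tau_mf, tau_mb = agent$tau_mb,
        w_specific = agent$w_specific, w_flexible = agent$w_flexible,
        lapse_rate = agent$lapse_rate, missing_rate = agent$missing_rate,
        tree_seed = seeds[i, 1L], schedule_seed = seeds[i, 2L],
        agent_seed = seeds[i, 3L], stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects, truth = do.call(rbind, truth),
                 master_seed = as.integer(master_seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$truth), " subjects (",
      paste(names(table(x$truth$group)), table(x$truth$group),
            sep = ": ", collapse = ", "),
      "), master_seed ", x$master_seed, "\n", sep = "")
  invisible(x)
}
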