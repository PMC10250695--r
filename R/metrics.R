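#' Model-based preference
#'
#' Percentage of (non-missing) trials in the mask on which the
#' model-based per-trial likelihood strictly exceeds the model-free one.
#' Ties count as non-model-based.
#'
#' @param lik_mf,lik_mb Aligned per-trial likelihood traces (NA for
#'   missing trials), e.g. `fit$per_trial_likelihood`.
#' @param mask Logical vector selecting the trials (e.g. one condition).
#' @return Percentage in \[0, 100\].
#' @export
mb_preference <- function(lik_mf, lik_mb, mask = rep(TRUE, length(lik_mf))) {
  stopifnot(length(lik_mf) == length(lik_mb), length(mask) == length(lik_mf))
  keep <- mask & !is.na(lik_mf) & !is.na(lik_mb)
  if (!any(keep)) stop("no non-missing trials in mask")
  100 * mean(lik_mb[keep] > lik_mf[keep])
}

# Dominant system per trial; ties inherit the previous trial's dominance
# (the first trial defaults to "mf", consistent with the tie rule of
# mb_preference). Missing trials are NA.
dominant_system <- function(lik_mf, lik_mb) {
  n <- length(lik_mf)
  dom <- rep(NA_character_, n)
  prev <- "mf"
  for (t in seq_len(n)) {
    if (is.na(lik_mf[t]) || is.na(lik_mb[t])) next
    dom[t] <- if (lik_mb[t] > lik_mf[t]) {
      "mb"
    } else if (lik_mb[t] < lik_mf[t]) {
      "mf"
    } else {
      prev
    }
    prev <- dom[t]
  }
  dom
}

#' System switching rate
#'
#' Percentage of consecutive trial pairs (within the masked, non-missing
#' sequence, in session order) whose dominant learning system differs.
#' All blocks of a condition are concatenated in session order; block
#' boundaries within a condition are not breaks, while pairs straddling a
#' condition change never arise because the measure is computed per
#' condition mask.
#'
#' @param dominant Character vector of "mf"/"mb" (NA = missing), e.g. from
#'   the per-trial likelihood traces via ties-inherit-previous.
#' @param mask Logical trial mask.
#' @return Percentage in \[0, 100\].
#' @export
switching_rate <- function(dominant, mask = rep(TRUE, length(dominant))) {
  d <- dominant[mask & !is.na(dominant)]
  if (length(d) < 2L) stop("need at least 2 non-missing trials in mask")
  100 * mean(d[-1L] != d[-length(d)])
}

#' Arbitration score
#'
#' Ratio of the model-based preference in the specific condition to that
#' in the flexible condition. Values above 1 indicate that model-based
#' control is deployed preferentially where it is required. Undefined
#' (NA) when the flexible preference is 0.
#'
#' @param pref_specific,pref_flexible Preference percentages.
#' @return The ratio, or NA.
#' @export
arbitration_score <- function(pref_specific, pref_flexible) {
  if (is.na(pref_flexible) || pref_flexible <= 0) return(NA_real_)
  pref_specific / pref_flexible
}

#' Task performance per condition
#'
#' Mean paid coins per non-missing trial, and choice optimality: the
#' percentage of trials on which the subject's two decisions both lie in
#' the optimal action sets of the true-model oracle
#' ([optimal_policy_value()]) for that trial's condition, goal and
#' uncertainty (first decision at the root, second at the stage-2 state
#' actually reached). Any action tied for optimal counts as optimal.
#'
#' @param session Session data.frame (training trials are excluded).
#' @param tree The subject's `decision_tree`.
#' @return data.frame with one row per condition present: `condition`,
#'   `n_trials`, `mean_coins`, `choice_optimality`.
#' @export
performance <- function(session, tree) {
  session <- subset_phase(session, "main")
  live <- session[!session$missing, , drop = FALSE]
  key <- paste(live$condition, live$goal_color, live$uncertainty)
  oracle <- lapply(split(seq_len(nrow(live)), key), function(idx) {
    tr <- live[idx[1L], ]
    optimal_policy_value(tree, tr$condition,
                         if (tr$condition == "specific") tr$goal_color,
                         tr$uncertainty)
  })
  opt <- vapply(seq_len(nrow(live)), function(i) {
    o <- oracle[[key[i]]]
    (live$a1[i] %in% o$optimal[[1L]]) &&
      (live$a2[i] %in% o$optimal[[live$s2[i] + 1L]])
  }, logical(1L))
  res <- lapply(split(seq_len(nrow(live)), live$condition), function(idx) {
    data.frame(condition = live$condition[idx[1L]], n_trials = length(idx),
               mean_coins = mean(live$reward_paid[idx]),
               choice_optimality = 100 * mean(opt[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-subject strategy metrics
#'
#' Combines the fitted per-trial likelihood traces of the two systems
#' with the session log into the dependent measures reported per subject
#' and condition: model-based preference, system switching rate, mean
#' coins, choice optimality, and the overall arbitration score.
#'
#' @param session Session data.frame.
#' @param tree The subject's `decision_tree`.
#' @param fit_mf,fit_mb `fit_result` objects for the two systems, fitted
#'   on the same (main-phase) trials.
#' @param subject_id Identifier for the output row; defaults to the
#'   session's.
#' @return One-row data.frame with columns `subject_id`,
#'   `mb_pref_specific`, `mb_pref_flexible`, `switch_specific`,
#'   `switch_flexible`, `mean_coins_specific`, `mean_coins_flexible`,
#'   `optimality_specific`, `optimality_flexible`, `arbitration_score`.
#' @export
strategy_metrics <- function(session, tree, fit_mf, fit_mb,
                             subject_id = NULL) {
  session <- subset_phase(session, "main")
  stopifnot(fit_mf$learner_kind == "mf", fit_mb$learner_kind == "mb",
            length(fit_mf$per_trial_likelihood) == nrow(session),
            length(fit_mb$per_trial_likelihood) == nrow(session))
  lmf <- fit_mf$per_trial_likelihood
  lmb <- fit_mb$per_trial_likelihood
  dom <- dominant_system(lmf, lmb)
  perf <- performance(session, tree)
  perf_row <- function(cond, col) {
    v <- perf[perf$condition == cond, col]
    if (length(v) == 0L) NA_real_ else v
  }
  msk <- function(cond) session$condition == cond
  pref_s <- mb_preference(lmf, lmb, msk("specific"))
  pref_f <- mb_preference(lmf, lmb, msk("flexible"))
  data.frame(
    subject_id = subject_id %||% session$subject_id[1L],
    mb_pref_specific = pref_s, mb_pref_flexible = pref_f,
    switch_specific = switching_rate(dom, msk("specific")),
    switch_flexible = switching_rate(dom, msk("flexible")),
    mean_coins_specific = perf_row("specific", "mean_coins"),
    mean_coins_flexible = perf_row("flexible", "mean_coins"),
    optimality_specific = perf_row("specific", "choice_optimality"),
    optimality_flexible = perf_row("flexible", "choice_optimality"),
    arbitration_score = arbitration_score(pref_s, pref_f),
    stringsAsFactors = FALSE
  )
}

#' Fit both systems and compute metrics for a whole cohort
#'
#' Convenience driver: for every simulated subject, fits the model-free
#' and model-based learners by maximum likelihood and assembles the
#' strategy-metrics table, joined with the cohort's group labels.
#'
#' @param cohort A [make_cohort()] object.
#' @param n_restarts Restarts per fit (scale down for smoke runs).
#' @param seed Base seed for the fits (one derived seed per subject).
#' @param verbose Print a line per subject.
#' @return List with `metrics` (data.frame, one row per subject, with a
#'   `group` column) and `fits` (per-subject list of the two
#'   `fit_result`s).
#' @export
cohort_metrics <- function(cohort, n_restarts = 200L, seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- vector("list", length(cohort$subjects))
  fits <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    su <- cohort$subjects[[i]]
    fmf <- fit_learner(su$session, su$tree, "mf", n_restarts = n_restarts,
                       seed = seed + 2L * i)
    fmb <- fit_learner(su$session, su$tree, "mb", n_restarts = n_restarts,
                       seed = seed + 2L * i + 1L)
    m <- strategy_metrics(su$session, su$tree, fmf, fmb,
                          subject_id = su$subject_id)
    m$group <- su$group
    rows[[i]] <- m
    fits[[i]] <- list(mf = fmf, mb = fmb)
    if (verbose) {
      message(su$subject_id, ": mb_pref spec/flex = ",
              round(m$mb_pref_specific, 1), "/",
              round(m$mb_pref_flexible, 1))
    }
  }
  names(fits) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  list(metrics = do.call(rbind, rows), fits = fits)
}
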