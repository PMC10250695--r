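SESSION_COLUMNS <- c("subject_id", "trial_index", "block_index", "condition",
                     "uncertainty", "goal_color", "s1", "a1", "s2", "a2",
                     "s3", "coins_shown", "reward_paid", "missing")

#' Validate a session log against a decision tree
#'
#' Checks the structural invariants of the trial log: every trial starts
#' at the root, each visited state is a candidate successor of the
#' previous (state, action), the shown coins match the terminal's value,
#' and the paid reward obeys the goal rule (full coins in the flexible
#' condition; goal-colored coins only in the specific condition). The
#' first violation is reported with its row number.
#'
#' @param session Session data.frame.
#' @param tree The `decision_tree` the session was played on.
#' @return The session, invisibly.
#' @export
validate_session <- function(session, tree) {
  need <- setdiff(SESSION_COLUMNS, names(session))
  if (length(need) > 0L) {
    stop("session is missing columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(session))) {
    tr <- session[i, ]
    if (isTRUE(tr$missing)) next
    fail <- function(msg) stop("session row ", i, ": ", msg)
    if (tr$s1 != 0L) fail("s1 is not the root state")
    if (!tr$a1 %in% c(0L, 1L) || !tr$a2 %in% c(0L, 1L)) {
      fail("actions must be 0 (left) or 1 (right)")
    }
    if (!tr$s2 %in% tree$succ[pair_index(tr$s1, tr$a1), ]) {
      fail(paste0("s2 = ", tr$s2, " is not a candidate successor of (",
                  tr$s1, ", ", tr$a1, ")"))
    }
    if (!tr$s3 %in% tree$succ[pair_index(tr$s2, tr$a2), ]) {
      fail(paste0("s3 = ", tr$s3, " is not a candidate successor of (",
                  tr$s2, ", ", tr$a2, ")"))
    }
    coins <- tree$terminal_value[tr$s3 - tree$n2]
    if (!isTRUE(all.equal(tr$coins_shown, coins))) {
      fail("coins_shown does not match the terminal value")
    }
    paid_ok <- if (tr$condition == "flexible") {
      isTRUE(all.equal(tr$reward_paid, coins))
    } else {
      goal_hit <- tree$terminal_color[tr$s3 - tree$n2] == tr$goal_color
      isTRUE(all.equal(tr$reward_paid, if (goal_hit) coins else 0))
    }
    if (!paid_ok) fail("reward_paid violates the goal rule")
  }
  invisible(session)
}

#' Read and write session logs as CSV
#'
#' One row per trial with the standard column set. Training trials are
#' identified by negative `block_index`; a `phase` column is recomputed on
#' read.
#'
#' @param session Session data.frame.
#' @param path File path.
#' @param tree Optional `decision_tree` to validate against on read.
#' @return `read_session` returns the session data.frame.
#' @export
write_session <- function(session, path) {
  write.csv(session[, SESSION_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, tree = NULL) {
  session <- read.csv(path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  session$missing <- as.logical(session$missing)
  session$phase <- ifelse(session$block_index >= 1L, "main", "training")
  if (!is.null(tree)) validate_session(session, tree)
  session
}

#' Read and write decision trees as JSON
#'
#' @param tree A `decision_tree`.
#' @param path File path.
#' @return `read_tree` returns the `decision_tree`.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(list(
    n2 = tree$n2, n3 = tree$n3, succ = tree$succ,
    terminal_value = tree$terminal_value,
    terminal_color = tree$terminal_color, tree_seed = tree$tree_seed,
    config = unclass(tree$config)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  succ <- matrix(as.integer(x$succ), ncol = 2L,
                 dimnames = list(NULL, c("likely", "unlikely")))
  tree <- structure(list(
    n2 = as.integer(x$n2), n3 = as.integer(x$n3), succ = succ,
    terminal_value = as.numeric(x$terminal_value),
    terminal_color = as.character(x$terminal_color),
    tree_seed = as.integer(x$tree_seed),
    config = tree_config(x$config$n2, x$config$n3,
                         as.numeric(x$config$terminal_values))
  ), class = "decision_tree")
  validate_tree(tree)
  tree
}

#' Read and write fit results as JSON
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @return `read_fit` returns the `fit_result`.
#' @export
write_fit <- function(fit, path) {
  x <- unclass(fit)
  x$params <- as.list(x$params)        # keep names in JSON
  x$decision_prob <- unname(x$decision_prob)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- unlist(x$params)
  x$decision_prob <- matrix(as.numeric(x$decision_prob), ncol = 2L)
  x$n_restarts <- as.integer(x$n_restarts)
  structure(x, class = "fit_result")
}

#' Read and write strategy-metrics tables as CSV
#'
#' @param metrics Metrics data.frame.
#' @param path File path.
#' @return `read_metrics` returns the data.frame.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full pipeline: simulate, fit, metrics, stats
#'
#' Executes the stages in order on a synthetic cohort and writes all
#' artifacts (per-subject session CSVs and tree JSONs, fit JSONs, the
#' metrics table, group statistics, and a run manifest with seeds and
#' file hashes) into `out_dir`. Rerunning with an identical config
#' reproduces identical outputs.
#'
#' @param config A named list (or path to a YAML/JSON file) with any of:
#'   `n_per_group`, `master_seed`, `n_restarts`, `fit_seed`, `training`,
#'   `groups` (named list of [cohort_group()] argument lists),
#'   `covariates`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(list(n_per_group = 4L, master_seed = 1L,
                                n_restarts = 20L, fit_seed = 1L,
                                training = FALSE, groups = NULL,
                                covariates = character()),
                           config)
  groups <- if (is.null(cfg$groups)) {
    default_cohort_groups()
  } else {
    lapply(cfg$groups, function(g) do.call(cohort_group, g))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("sessions", "trees", "fits")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  manifest <- list(config = cfg, package_version =
                     as.character(utils::packageVersion("arbitrl")),
                   complete = FALSE, files = list())
  on.exit(jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE))

  cohort <- make_cohort(cfg$n_per_group, groups,
                        master_seed = cfg$master_seed,
                        training = isTRUE(cfg$training))
  for (su in cohort$subjects) {
    write_session(su$session,
                  file.path(out_dir, "sessions",
                            paste0(su$subject_id, ".csv")))
    write_tree(su$tree,
               file.path(out_dir, "trees", paste0(su$subject_id, ".json")))
  }
  write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)

  cm <- cohort_metrics(cohort, n_restarts = cfg$n_restarts,
                       seed = cfg$fit_seed)
  for (id in names(cm$fits)) {
    write_fit(cm$fits[[id]]$mf,
              file.path(out_dir, "fits", paste0(id, "_mf.json")))
    write_fit(cm$fits[[id]]$mb,
              file.path(out_dir, "fits", paste0(id, "_mb.json")))
  }
  write_metrics(cm$metrics, file.path(out_dir, "metrics.csv"))

  measures <- c("mb_pref_specific", "mb_pref_flexible", "switch_specific",
                "switch_flexible", "mean_coins_specific",
                "mean_coins_flexible", "optimality_specific",
                "optimality_flexible", "arbitration_score")
  stats_out <- list(
    group_comparisons = lapply(setNames(measures, measures), function(m) {
      unclass(compare_groups(cm$metrics, m, "group",
                             covariates = cfg$covariates))
    }),
    paired_and_correlational = tryCatch(
      paired_and_correlational(cm$metrics, "group"),
      error = function(e) conditionMessage(e))   # tiny demo cohorts
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- substring(names(manifest$files),
                                     nchar(out_dir) + 2L)
  manifest$complete <- TRUE
  invisible(manifest)
}
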