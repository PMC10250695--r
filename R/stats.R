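#' Group comparison: one-way ANOVA or ANCOVA with post-hoc contrasts
#'
#' Omnibus test for a group effect on one measure, optionally adjusting
#' for covariates (linear-model ANCOVA with the group term entered after
#' the covariates). Post-hoc pairwise group contrasts are computed from
#' the fitted model with both uncorrected and Tukey-corrected p values;
#' the correction to report is the analyst's choice.
#'
#' @param data data.frame of per-subject measures.
#' @param measure Column name of the dependent measure.
#' @param group Column name of the group factor (>= 2 levels, >= 2
#'   subjects each).
#' @param covariates Character vector of covariate column names.
#' @param welch Use Welch's heteroscedasticity-robust F (only without
#'   covariates).
#' @return Object of class `group_comparison`: `measure`, `groups`,
#'   `F`, `df`, `p`, `posthoc` (data.frame with `pair`, `estimate`, `se`,
#'   `t`, `p_unadjusted`, `p_tukey`), `covariates`, `degenerate`.
#' @export
compare_groups <- function(data, measure, group, covariates = character(),
                           welch = FALSE) {
  y <- data[[measure]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 subjects each")
  }
  if (length(unique(y[!is.na(y)])) <= 1L) {
    return(structure(list(measure = measure, groups = levels(g),
                          F = NA_real_, df = c(NA, NA), p = NA_real_,
                          posthoc = NULL, covariates = covariates,
                          degenerate = TRUE),
                     class = "group_comparison"))
  }
  if (welch) {
    if (length(covariates) > 0L) stop("welch = TRUE supports no covariates")
    ow <- stats::oneway.test(y ~ g)
    return(structure(list(measure = measure, groups = levels(g),
                          F = unname(ow$statistic),
                          df = unname(ow$parameter), p = unname(ow$p.value),
                          posthoc = NULL, covariates = character(),
                          degenerate = FALSE),
                     class = "group_comparison"))
  }
  df_model <- data.frame(.y = y, .g = g,
                         data[, covariates, drop = FALSE])
  rhs <- paste(c(covariates, ".g"), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = df_model)
  an <- anova(fit)                      # sequential: group adjusted for covs
  grow <- an[".g", ]
  k <- nlevels(g)
  df_res <- fit$df.residual

  # pairwise contrasts of (covariate-adjusted) group means
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  eff <- setNames(numeric(k), levels(g))   # group effects relative to level 1
  for (lv in levels(g)[-1L]) eff[lv] <- cf[paste0(".g", lv)]
  pairs <- utils::combn(levels(g), 2L)
  posthoc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    cvec <- setNames(rep(0, length(cf)), names(cf))
    if (g1 != levels(g)[1L]) cvec[paste0(".g", g1)] <- 1
    if (g2 != levels(g)[1L]) cvec[paste0(".g", g2)] <- -1
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    data.frame(pair = paste(g1, "-", g2), estimate = est, se = se, t = tval,
               p_unadjusted = 2 * pt(-abs(tval), df_res),
               p_tukey = ptukey(abs(tval) * sqrt(2), k, df_res,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(measure = measure, groups = levels(g),
                 F = grow[["F value"]], df = c(grow[["Df"]], df_res),
                 p = grow[["Pr(>F)"]], posthoc = posthoc,
                 covariates = covariates, degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<group_comparison> ", x$measure, ": degenerate (constant measure)\n",
        sep = "")
    return(invisible(x))
  }
  cat("<group_comparison> ", x$measure,
      if (length(x$covariates)) paste0(" | ", paste(x$covariates,
                                                    collapse = ", ")),
      ": F(", paste(x$df, collapse = ", "), ") = ", signif(x$F, 4),
      ", p = ", signif(x$p, 3), "\n", sep = "")
  if (!is.null(x$posthoc)) {
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Paired condition test and preference-performance correlations
#'
#' The manipulation check and brain-behavior-style correlations computed
#' per group on a strategy-metrics table: a paired t-test of the
#' model-based preference across conditions (specific vs flexible), and
#' Pearson correlations of the within-condition preference with the
#' within-condition mean coins.
#'
#' @param metrics Strategy-metrics data.frame (see [strategy_metrics()]).
#' @param group Optional name of a group column; omit for a single group.
#' @return data.frame with one row per group: `group`, `n`, `t`, `df`,
#'   `p_paired`, `r_specific`, `p_r_specific`, `r_flexible`,
#'   `p_r_flexible`.
#' @export
paired_and_correlational <- function(metrics, group = NULL) {
  split_idx <- if (is.null(group)) {
    list(all = seq_len(nrow(metrics)))
  } else {
    split(seq_len(nrow(metrics)), metrics[[group]])
  }
  out <- lapply(names(split_idx), function(g) {
    m <- metrics[split_idx[[g]], , drop = FALSE]
    if (nrow(m) < 3L) stop("need >= 3 subjects per group")
    d <- m$mb_pref_specific - m$mb_pref_flexible
    tt <- if (stats::sd(d) == 0) {
      # identical paired columns: define t = 0 rather than 0/0
      list(statistic = c(t = 0), parameter = c(df = length(d) - 1L),
           p.value = 1)
    } else {
      t.test(m$mb_pref_specific, m$mb_pref_flexible, paired = TRUE)
    }
    cs <- cor.test(m$mb_pref_specific, m$mean_coins_specific)
    cf <- cor.test(m$mb_pref_flexible, m$mean_coins_flexible)
    data.frame(group = g, n = nrow(m), t = unname(tt$statistic),
               df = unname(tt$parameter), p_paired = tt$p.value,
               r_specific = unname(cs$estimate), p_r_specific = cs$p.value,
               r_flexible = unname(cf$estimate), p_r_flexible = cf$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
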