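#' Per-condition mean and standard error
#'
#' Summarizes an endpoint table as mean +/- standard error (sd / sqrt(n))
#' per condition, the form in which assay endpoints are reported.
#'
#' @param table data frame with columns `condition` and `value` (one row per
#'   replicate measurement).
#' @return Data frame with columns `condition`, `n`, `mean`, `se` (`NA` for
#'   n = 1, where no variance estimate exists).
#' @export
summarize_groups <- function(table) {
  .check_group_table(table, min_per_group = 1L)
  agg <- lapply(split(table$value, table$condition), function(v) {
    c(n = length(v), mean = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- data.frame(condition = names(agg),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    se = vapply(agg, `[[`, numeric(1), "se"))
  rownames(out) <- NULL
  out
}

.check_group_table <- function(table, min_per_group = 2L) {
  stopifnot(is.data.frame(table),
            all(c("condition", "value") %in% names(table)))
  if (nrow(table) == 0L) stop("empty group table")
  if (any(!is.finite(table$value))) stop("non-finite values in group table")
  ns <- table(table$condition)
  if (any(ns < min_per_group))
    stop("condition(s) with fewer than ", min_per_group, " values: ",
         paste(names(ns)[ns < min_per_group], collapse = ", "))
  invisible(ns)
}

#' Compare endpoint values between conditions
#'
#' One-way ANOVA across all conditions, followed by Tukey's HSD post-hoc test
#' when more than two conditions are present; with exactly two conditions a
#' two-sample t-test is performed instead (Student's pooled-variance by
#' default, Welch optionally). Differences are flagged significant at
#' `p <= alpha`.
#'
#' @param table data frame with columns `condition`, `value` (and optionally
#'   `replicate`); at least 2 conditions with at least 2 values each.
#' @param alpha significance level. Default 0.05.
#' @param var_equal use the pooled-variance t-test (TRUE, default) or Welch.
#' @return List of class `group_comparison`: `n_conditions`, `anova`
#'   (list with `F`, `df`, `p`), `pairwise` (data frame with `group1`,
#'   `group2`, `estimate` = mean difference, `p`, `p_adjusted`, `significant`;
#'   for two conditions `p_adjusted` equals the t-test `p` and `t` is
#'   included), `method`, `alpha`.
#' @export
compare_groups <- function(table, alpha = 0.05, var_equal = TRUE) {
  .check_group_table(table, min_per_group = 2L)
  table$condition <- factor(table$condition)
  k <- nlevels(table$condition)
  if (k < 2L) stop("at least 2 conditions are required")
  fit <- stats::aov(value ~ condition, data = table)
  an <- summary(fit)[[1L]]
  anova_res <- list(F = an[["F value"]][1L],
                    df = c(an[["Df"]][1L], an[["Df"]][2L]),
                    p = an[["Pr(>F)"]][1L])
  if (k == 2L) {
    lev <- levels(table$condition)
    a <- table$value[table$condition == lev[1L]]
    b <- table$value[table$condition == lev[2L]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: both groups constant; declare by mean difference alone
      tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(b) - mean(a))
      pval <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(b, a, var.equal = var_equal)
      tstat <- unname(tt$statistic)
      pval <- tt$p.value
    }
    pw <- data.frame(group1 = lev[1L], group2 = lev[2L],
                     estimate = mean(b) - mean(a),
                     t = tstat,
                     p = pval, p_adjusted = pval,
                     significant = pval <= alpha)
    method <- if (var_equal) "Student t-test (pooled variance)" else "Welch t-test"
  } else {
    tk <- stats::TukeyHSD(fit)$condition
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    # unadjusted pairwise p for reference (same pooled-variance t-tests)
    unadj <- stats::pairwise.t.test(table$value, table$condition,
                                    p.adjust.method = "none", pool.sd = TRUE)
    getp <- function(g1, g2) {
      p <- unadj$p.value
      if (g1 %in% rownames(p) && g2 %in% colnames(p) && !is.na(p[g1, g2]))
        p[g1, g2] else p[g2, g1]
    }
    pw <- data.frame(
      group1 = vapply(pairs, `[[`, character(1), 2L),
      group2 = vapply(pairs, `[[`, character(1), 1L),
      estimate = tk[, "diff"],
      p = mapply(function(pr) getp(pr[2L], pr[1L]), pairs),
      p_adjusted = tk[, "p adj"],
      significant = tk[, "p adj"] <= alpha)
    rownames(pw) <- NULL
    method <- "one-way ANOVA + Tukey HSD"
  }
  structure(list(n_conditions = k, anova = anova_res, pairwise = pw,
                 method = method, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, alpha = %g\n", x$method, x$alpha))
  cat(sprintf("  ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df[1L], x$anova$df[2L], x$anova$F, x$anova$p))
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %s vs %s: diff = %.4g, adj. p = %.4g%s\n",
                r$group2, r$group1, r$estimate, r$p_adjusted,
                if (isTRUE(r$significant)) " *" else ""))
  }
  invisible(x)
}

#' Plain-text statistics report
#'
#' @param comparison a `group_comparison`.
#' @param summary optional output of [summarize_groups] to include.
#' @return Character vector of report lines.
#' @export
format_stats_report <- function(comparison, summary = NULL) {
  lines <- c(sprintf("Method: %s (alpha = %g)", comparison$method,
                     comparison$alpha),
             sprintf("ANOVA: F(%d, %d) = %.6g, p = %.6g",
                     comparison$anova$df[1L], comparison$anova$df[2L],
                     comparison$anova$F, comparison$anova$p))
  if (!is.null(summary)) {
    lines <- c(lines, "", "Group means (mean +/- SE, n):",
               sprintf("  %s: %.6g +/- %.6g (n = %d)", summary$condition,
                       summary$mean, summary$se, as.integer(summary$n)))
  }
  lines <- c(lines, "", "Pairwise comparisons:")
  pw <- comparison$pairwise
  lines <- c(lines, sprintf("  %s vs %s: diff = %.6g, adj. p = %.6g%s",
                            pw$group2, pw$group1, pw$estimate, pw$p_adjusted,
                            ifelse(pw$significant, "  [significant]", "")))
  lines
}
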